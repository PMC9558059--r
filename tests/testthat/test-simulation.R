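test_that("type-II sample generation honours n, r, ordering and determinism", {
  s <- generate_censored_sample(20, 16, mwed_params(1, 1, 1), seed = 1)
  expect_identical(s$n, 20L)
  expect_identical(s$r, 16L)
  expect_identical(length(s$observed), 16L)
  expect_false(is.unsorted(s$observed))
  s2 <- generate_censored_sample(20, 16, mwed_params(1, 1, 1), seed = 1)
  expect_identical(s$observed, s2$observed)
  full <- generate_censored_sample(20, 20, mwed_params(1, 1, 1), seed = 1)
  expect_identical(full$observed[1:16], s$observed)
})

test_that("study_config computes r from the censoring fraction", {
  cfg <- study_config(c(1, 1, 1), n = 20, replicates = 10)
  expect_identical(cfg$r, 16L)
  expect_identical(study_config(c(1, 1, 1), n = 100, replicates = 1)$r, 80L)
  expect_error(study_config(c(1, 1, 1), n = 4, censoring_fraction = 0.5,
                            replicates = 1), "r >= 3")
})

test_that("mse has its defining identities", {
  expect_identical(mse(c(1, 1, 1), 1), 0)
  expect_identical(mse(c(0, 2), 1), 1)
  x <- c(0.2, 1.4, 0.9, 2.2)
  expect_equal(mse(x, 1), (mean(x) - 1)^2 + mean((x - mean(x))^2),
               tolerance = 1e-12)
  expect_error(mse(numeric(0), 1), "no estimates")
})

test_that("identical study configurations give bit-identical results", {
  cfg <- study_config(c(1, 1, 1), n = 20, replicates = 8, seed = 7,
                      methods = "mle", max_drop_fraction = 0.9)
  r1 <- run_study(cfg)
  r2 <- run_study(cfg)
  expect_identical(r1$mean, r2$mean)
  expect_identical(r1$mse, r2$mse)
  expect_identical(attr(r1, "dropped"), attr(r2, "dropped"))
})

test_that("a full study reports all methods, parameters and the drop accounting", {
  cfg <- study_config(c(1, 1, 1), n = 50, replicates = 30, seed = 3,
                      max_drop_fraction = 0.9)
  res <- run_study(cfg)
  expect_setequal(unique(res$method), c("MLE", "SELF", "PLF", "QLF", "ELF"))
  expect_setequal(unique(res$parameter), c("theta", "sigma", "mu"))
  expect_identical(nrow(res), 15L)
  expect_true(all(is.finite(res$mean)))
  expect_true(all(res$mse >= 0))
  dr <- attr(res, "drop_reason")
  expect_identical(sum(dr), attr(res, "dropped"))
  expect_identical(attr(res, "kept") + attr(res, "dropped"), 30L)
})

test_that("estimator error decreases with sample size in a seeded MLE study", {
  mses <- vapply(c(20, 100, 500), function(n) {
    cfg <- study_config(c(1, 2, 1), n = n, replicates = 40, seed = 91,
                        methods = "mle", max_drop_fraction = 0.9)
    res <- run_study(cfg)
    mean(res$mse[res$method == "MLE" & res$parameter == "sigma"])
  }, numeric(1))
  expect_true(mses[3] < mses[1])
})
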