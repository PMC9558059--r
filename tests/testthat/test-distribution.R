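test_that("density, cdf, reliability and hazard match their closed forms", {
  expect_equal(dmwed(1, 1, 1, 1), exp(2 - exp(1)), tolerance = 1e-12)
  expect_equal(pmwed(log(2), 1, 1, 1), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(smwed(log(2), 1, 1, 1), exp(-1), tolerance = 1e-12)
  expect_equal(hmwed(1, 1, 1, 1), exp(1), tolerance = 1e-12)
  expect_identical(pmwed(0, 2, 0.5, 0.1), 0)
  expect_identical(smwed(0, 2, 0.5, 0.1), 1)
})

test_that("density at the origin follows the continuity convention in sigma", {
  expect_identical(dmwed(0, 1, 2, 1), 0)          # sigma > 1
  expect_equal(dmwed(0, 1, 1, 3), 3)              # sigma = 1: sigma * mu
  expect_identical(dmwed(0, 1, 0.5, 1), Inf)      # sigma < 1
})

test_that("cdf and quantile are mutual inverses across the parameter grid", {
  u <- c(1e-6, 0.01, 0.1, 0.37, 0.5, 0.9, 0.99, 1 - 1e-6)
  for (p in param_grid) {
    q <- qmwed(u, p[1], p[2], p[3])
    expect_true(all(diff(q) > 0))
    expect_equal(pmwed(q, p[1], p[2], p[3]), u, tolerance = 1e-10)
  }
  expect_equal(qmwed(1 - exp(-1), 1, 1, 1), log(2), tolerance = 1e-12)
})

test_that("the density integrates to one and differentiates the cdf", {
  for (p in param_grid[c(1, 5, 9, 12)]) {
    upper <- qmwed(1 - 1e-9, p[1], p[2], p[3])
    mid <- qmwed(0.5, p[1], p[2], p[3])
    # split at the median: for sigma < 1 the density has an integrable
    # singularity at the origin
    total <- stats::integrate(function(x) dmwed(x, p[1], p[2], p[3]),
                              0, mid, rel.tol = 1e-8)$value +
      stats::integrate(function(x) dmwed(x, p[1], p[2], p[3]),
                       mid, upper, rel.tol = 1e-8)$value
    expect_equal(total, 1, tolerance = 1e-4)
    x <- qmwed(c(0.2, 0.5, 0.8), p[1], p[2], p[3])
    h <- 1e-5 * x
    num <- (pmwed(x + h, p[1], p[2], p[3]) - pmwed(x - h, p[1], p[2], p[3])) / (2 * h)
    expect_equal(dmwed(x, p[1], p[2], p[3]), num, tolerance = 1e-6)
  }
})

test_that("hazard equals density over reliability and switches shape at sigma = 1", {
  for (p in param_grid[c(1, 2, 9)]) {
    # interior quantiles: beyond them the reliability underflows and the
    # ratio definition is 0/0 in double precision
    xq <- qmwed(seq(0.05, 0.95, by = 0.05), p[1], p[2], p[3])
    expect_equal(hmwed(xq, p[1], p[2], p[3]),
                 dmwed(xq, p[1], p[2], p[3]) / smwed(xq, p[1], p[2], p[3]),
                 tolerance = 1e-12)
  }
  x <- seq(0.1, 3, by = 0.1)
  # increasing hazard for sigma >= 1
  expect_true(all(diff(hmwed(x, 1, 2, 1)) > 0))
  expect_true(all(diff(hmwed(x, 1, 1, 1)) > 0))
  # bathtub for sigma < 1: decreasing then increasing, one interior minimum
  xg <- exp(seq(log(0.01), log(10), length.out = 200))
  hz <- hmwed(xg, 1, 0.5, 1)
  sign_changes <- sum(diff(sign(diff(hz))) != 0)
  expect_identical(sign_changes, 1L)
  expect_true(which.min(hz) > 1 && which.min(hz) < length(hz))
})

test_that("reliability complements the cdf exactly", {
  x <- seq(0, 5, by = 0.25)
  for (p in param_grid) {
    expect_equal(smwed(x, p[1], p[2], p[3]) + pmwed(x, p[1], p[2], p[3]),
                 rep(1, length(x)), tolerance = 1e-15)
  }
})

test_that("domain violations are rejected", {
  expect_error(dmwed(-1, 1, 1, 1), "nonnegative")
  expect_error(hmwed(0, 1, 1, 1), "x > 0")
  expect_error(qmwed(0, 1, 1, 1), "inside")
  expect_error(qmwed(1, 1, 1, 1), "inside")
  expect_error(mwed_params(0, 1, 1), "positive")
  expect_error(mwed_params(1, -1, 1), "positive")
  expect_error(dmwed(1, 1, NA, 1), "positive")
})

test_that("the sampler is seed-deterministic and leaves the caller's RNG alone", {
  a <- rmwed(5, 1, 2, 0.5, seed = 7)
  b <- rmwed(5, 1, 2, 0.5, seed = 7)
  expect_identical(a, b)
  set.seed(123)
  u1 <- runif(1)
  set.seed(123)
  invisible(rmwed(10, 1, 1, 1, seed = 99))
  expect_identical(runif(1), u1)
})

test_that("samples follow the distribution (KS) and match the quadrature mean", {
  x <- rmwed(10000, 1, 1, 1, seed = 42)
  ks <- suppressWarnings(stats::ks.test(x, function(q) pmwed(q, 1, 1, 1)))
  expect_gt(ks$p.value, 0.01)
  m_quad <- stats::integrate(function(t) t * dmwed(t, 1, 1, 1), 0, 15,
                             rel.tol = 1e-10)$value
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - m_quad), 3 * se)
})
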