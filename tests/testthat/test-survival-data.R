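test_that("the leukemia dataset D1 loads exactly as printed", {
  d1 <- mwed_dataset("D1")
  expect_identical(nrow(d1$records), 30L)
  expect_identical(sum(d1$records$event == 0L), 5L)
  expect_identical(sort(d1$records$time[d1$records$event == 0L]),
                   c(31, 45, 50, 71, 85))
  expect_identical(max(d1$records$time), 91)
  expect_identical(d1$unit, "weeks")
  # duplicated event times preserved verbatim
  tt <- d1$records$time[d1$records$event == 1L]
  expect_identical(sum(tt == 1), 2L)
  expect_identical(sum(tt == 4), 2L)
  expect_identical(sum(tt == 6), 3L)
})

test_that("the bile-duct dataset D2 loads exactly as printed", {
  d2 <- mwed_dataset("D2")
  expect_identical(nrow(d2$records), 22L)
  expect_identical(sum(d2$records$event == 0L), 3L)
  expect_identical(sort(d2$records$time[d2$records$event == 0L]),
                   c(79, 82, 446))
  expect_identical(range(d2$records$time), c(30, 777))
  expect_identical(d2$unit, "days")
  expect_error(mwed_dataset("D3"))
})

test_that("dataset fixtures roundtrip through the CSV writer and reader", {
  for (nm in c("D1", "D2")) {
    rec <- mwed_dataset(nm)$records
    f <- tempfile(fileext = ".csv")
    write_survival_csv(rec, f)
    back <- read_survival_csv(f)
    expect_identical(back$time, rec$time)
    expect_identical(back$event, rec$event)
  }
})

test_that("the product-limit curve matches hand computation", {
  km <- km_estimator(survival_records(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(step_curve_at(km, c(1, 2, 3)), c(2, 1, 0) / 3, tolerance = 1e-12)
  expect_identical(step_curve_at(km, 0), 1)
  # censoring at 2: S(1) = 2/3, S(3) = 2/3 * (1 - 1/1) = 0
  km2 <- km_estimator(survival_records(c(1, 2, 3), c(1, 0, 1)))
  expect_equal(step_curve_at(km2, 1), 2 / 3, tolerance = 1e-12)
  expect_equal(step_curve_at(km2, 2.5), 2 / 3, tolerance = 1e-12)
  expect_equal(step_curve_at(km2, 3), 0)
})

test_that("without censoring the product-limit curve is the empirical complement", {
  x <- c(2, 5, 5, 9, 11)
  km <- km_estimator(survival_records(x, rep(1, 5)))
  expect_equal(step_curve_at(km, sort(unique(x))),
               1 - stats::ecdf(x)(sort(unique(x))), tolerance = 1e-12)
})

test_that("empirical-fit MSE is zero iff the curves agree at the evaluation points", {
  rec <- mwed_dataset("D1")$records
  km <- km_estimator(rec)
  emp_cdf <- function(t) 1 - step_curve_at(km, t)
  expect_identical(empirical_fit_mse(rec, emp_cdf), 0)
  expect_gt(empirical_fit_mse(rec, function(t) rep(0.5, length(t))), 0)
})

test_that("both datasets fit under all five methods with sane curves", {
  for (nm in c("D1", "D2")) {
    fd <- fit_dataset(mwed_dataset(nm), prior = "gamma")
    expect_true(all(is.finite(fd$params)))
    expect_true(all(fd$params > 0))
    expect_identical(rownames(fd$params), c("MLE", "SELF", "PLF", "QLF", "ELF"))
    # every fitted cdf within [0,1] and nondecreasing; reliability the complement
    expect_true(all(fd$cdf >= 0 & fd$cdf <= 1))
    expect_true(all(apply(fd$cdf, 2, function(v) all(diff(v) >= -1e-12))))
    expect_equal(fd$cdf + fd$reliability,
                 matrix(1, nrow(fd$cdf), ncol(fd$cdf),
                        dimnames = dimnames(fd$cdf)), tolerance = 1e-12)
    # KM curve starts at 1 and is nonincreasing
    expect_true(all(diff(fd$km$surv) <= 1e-12))
    expect_lte(max(fd$km$surv), 1)
    expect_true(all(fd$fit_mse >= 0))
  }
})
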