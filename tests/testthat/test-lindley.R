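test_that("with flat prior, zero third derivatives and linear h the engine returns h(MLE)", {
  S <- matrix(c(0.5, 0.1, 0, 0.1, 0.4, 0.05, 0, 0.05, 0.3), 3, 3)
  bundle <- structure(list(mle = mwed_params(1.2, 0.9, 1.1),
                           hessian = -solve(S), third = array(0, c(3, 3, 3)),
                           S = S, rho = c(0, 0, 0)),
                      class = "derivative_bundle")
  h <- h_function(4.2, c(1, -2, 0.5), matrix(0, 3, 3))
  expect_identical(lindley_expectation(h, bundle), 4.2)
})

test_that("h_power and h_log carry the analytic derivatives of one-coordinate maps", {
  p <- mwed_params(0.8, 2, 0.5)
  h <- h_power(1, -2, p)
  expect_equal(h$value, 0.8^-2)
  expect_equal(h$gradient, c(-2 * 0.8^-3, 0, 0))
  expect_equal(h$hessian[1, 1], 6 * 0.8^-4)
  expect_identical(sum(abs(h$hessian[-1, -1])), 0)
  hl <- h_log(3, p)
  expect_equal(hl$value, log(0.5))
  expect_equal(hl$gradient, c(0, 0, 2))
  expect_equal(hl$hessian[3, 3], -4)
})

test_that("quadratic-posterior check: engine reproduces the exact Gaussian moment shift", {
  # For a Gaussian log-posterior (third derivatives zero) and h = p_t,
  # E[h] = mle_t + (S rho)_t exactly; the engine must reproduce it.
  S <- diag(c(0.04, 0.02, 0.09))
  rho <- c(0.5, -1, 0.2)
  bundle <- structure(list(mle = mwed_params(1, 1, 1), hessian = -solve(S),
                           third = array(0, c(3, 3, 3)), S = S, rho = rho),
                      class = "derivative_bundle")
  for (t in 1:3) {
    h <- h_power(t, 1, bundle$mle)
    expect_equal(lindley_expectation(h, bundle), 1 + (S %*% rho)[t],
                 tolerance = 1e-12)
  }
})

test_that("the expansion agrees with exact integration on a well-identified sample", {
  # large n: the asymptotic regime where the expansion is valid
  s <- generate_censored_sample(2000, 1600, mwed_params(1, 1, 1), seed = 77)
  prior <- elicit_gamma_prior(c(1, 1, 1), 1)
  fit <- fit_mwed_mle(s)
  bundle <- derivative_bundle(s, fit$params, log_prior_gradient(fit$params, prior))
  lin <- lindley_moments(bundle)
  quad <- posterior_moments_quadrature(s, prior, fit = fit)
  expect_lt(max(abs(lin - quad) / abs(quad)), 0.02)
  # approximate posterior variance is positive
  expect_gt(lin["theta", "m2"] - lin["theta", "m1"]^2, 0)
})

test_that("bayes_estimates collapses to the MLE under a flat prior at large n", {
  s <- generate_censored_sample(2000, 1600, mwed_params(1, 1, 1), seed = 77)
  fit <- fit_mwed_mle(s)
  est <- bayes_estimates(s, flat_prior(), method = "lindley", fit = fit)
  # the well-identified shapes collapse tightly; theta's posterior stays
  # wide even at n = 2000 (relative SE about 0.2), so its Bayes-MLE gap
  # is bounded by that scale rather than by 2%
  tol <- c(sigma = 0.02, mu = 0.10, theta = 0.15)
  for (par in names(tol)) {
    vals <- est$estimate[est$parameter == par]
    expect_equal(vals, rep(fit$params[[par]], 4), tolerance = tol[[par]])
  }
  # and the collapse tightens as n grows
  s_small <- generate_censored_sample(500, 400, mwed_params(1, 1, 1), seed = 77)
  fit_s <- fit_mwed_mle(s_small)
  est_s <- bayes_estimates(s_small, flat_prior(), method = "lindley", fit = fit_s)
  gap <- function(e, f) {
    max(abs(e$estimate[e$parameter == "sigma"] - f$params[["sigma"]]) /
          f$params[["sigma"]])
  }
  expect_lt(gap(est, fit), gap(est_s, fit_s))
})
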