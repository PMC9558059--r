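#' Posterior expectations by deterministic 3-D quadrature
#'
#' Evaluates the exact ratio of posterior integrals
#' \eqn{E[h|x] = \int h\, e^{\ell + G} d\Psi / \int e^{\ell + G} d\Psi}
#' by tensor-product Gauss-Legendre quadrature.  This is the slow,
#' assumption-free oracle against which the Lindley expansion
#' ([lindley_expectation()]) is validated.
#'
#' The integration is performed in log-parameter space (the Jacobian
#' \eqn{\prod_t \Psi_t} is included), over a box centred at the log MLE
#' with half-width `half_width` asymptotic standard errors per
#' coordinate (delta method).  If visible posterior mass reaches the
#' box boundary the box is widened once by 50% and the integral
#' recomputed; if mass still touches the boundary an error is thrown.
#'
#' @param h function of three vectors `(theta, sigma, mu)` returning a
#'   vector of values of the integrand, e.g. `function(th, sg, mu) th`.
#' @param d a [censored_sample()] or [survival_records()] object.
#' @param prior a [gamma_prior()].
#' @param nodes number of Gauss-Legendre nodes per dimension.
#' @param half_width box half-width in asymptotic standard errors.
#' @param fit optional pre-computed [fit_mwed_mle()] for `d`.
#' @return `posterior_expectation_quadrature()`: a single number.
#'   `posterior_moments_quadrature()`: the same 3x5 moment matrix
#'   layout as [lindley_moments()].
#' @export
posterior_expectation_quadrature <- function(h, d, prior = flat_prior(),
                                             nodes = 41, half_width = 8,
                                             fit = NULL) {
  grid <- .posterior_grid(d, prior, nodes = nodes, half_width = half_width, fit = fit)
  w <- grid$weights
  vals <- h(grid$params[, 1L], grid$params[, 2L], grid$params[, 3L])
  sum(w * vals) / sum(w)
}

#' @rdname posterior_expectation_quadrature
#' @export
posterior_moments_quadrature <- function(d, prior = flat_prior(), nodes = 41,
                                         half_width = 8, fit = NULL) {
  grid <- .posterior_grid(d, prior, nodes = nodes, half_width = half_width, fit = fit)
  w <- grid$weights / sum(grid$weights)
  out <- matrix(NA_real_, 3, 5,
                dimnames = list(c("theta", "sigma", "mu"),
                                c("m1", "m2", "minv1", "minv2", "mlog")))
  for (coord in 1:3) {
    v <- grid$params[, coord]
    out[coord, ] <- c(sum(w * v), sum(w * v^2), sum(w / v), sum(w / v^2),
                      sum(w * log(v)))
  }
  out
}

# Build the weighted parameter grid: Gauss-Legendre nodes in log space,
# weights = GL weight x posterior kernel x Jacobian (normalized by the
# kernel maximum for stability).  The box is sized from the POSTERIOR
# curvature (log-likelihood Hessian plus log-prior Hessian), so an
# informative prior keeps the box tight even where the likelihood is
# ridge-flat; the theta axis is additionally capped at the estimator's
# compactified parameter space (10 * max observed time), where mass at
# the cap is legitimate and not an integration failure.
.posterior_grid <- function(d, prior, nodes, half_width, fit, .widened = FALSE) {
  rec <- as_survival_records(d)
  stopifnot(inherits(prior, "gamma_prior"))
  if (is.null(fit)) fit <- fit_mwed_mle(rec)
  p_hat <- as.numeric(fit$params)

  bundle <- derivative_bundle(rec, fit$params)
  info_post <- -bundle$hessian + diag(pmax((prior$shapes - 1), 0) / p_hat^2)
  se <- tryCatch({
    S_post <- chol2inv(chol(info_post))
    sqrt(diag(S_post))
  }, error = function(e) sqrt(diag(bundle$S)))
  hw_cap <- if (.widened) 12 else 8
  hw <- pmin(pmax(half_width * se / p_hat, 1e-3), hw_cap)  # half-width, log units
  lo <- log(p_hat) - hw
  hi <- log(p_hat) + hw
  cap <- log(10 * max(rec$time))
  theta_capped <- hi[1L] >= cap
  if (theta_capped) hi[1L] <- cap

  gl <- lapply(1:3, function(t) pracma::gaussLegendre(nodes, lo[t], hi[t]))
  idx <- as.matrix(expand.grid(i = seq_len(nodes), j = seq_len(nodes),
                               k = seq_len(nodes)))
  lpar <- cbind(gl[[1L]]$x[idx[, 1L]], gl[[2L]]$x[idx[, 2L]], gl[[3L]]$x[idx[, 3L]])
  glw <- gl[[1L]]$w[idx[, 1L]] * gl[[2L]]$w[idx[, 2L]] * gl[[3L]]$w[idx[, 3L]]
  params <- exp(lpar)

  logkern <- .log_posterior_kernel_grid(rec, prior, params) + rowSums(lpar)
  M <- max(logkern)

  weights <- glw * exp(logkern - M)

  # mass-on-boundary check: probability share of the outermost node
  # layer (the capped theta face excepted: mass there reflects the
  # bounded parameter space, not a mis-sized box)
  outer_layer <- (idx[, 1L] == 1L) | (!theta_capped & idx[, 1L] == nodes) |
    (idx[, 2L] %in% c(1L, nodes)) | (idx[, 3L] %in% c(1L, nodes))
  if (sum(weights[outer_layer]) > 1e-3 * sum(weights)) {
    if (.widened) {
      stop("posterior mass reaches the integration boundary even after widening",
           call. = FALSE)
    }
    return(.posterior_grid(d, prior, nodes, half_width * 1.5, fit, .widened = TRUE))
  }

  list(params = params, weights = weights, fit = fit)
}

# Vectorized log posterior kernel (loglik + log prior) over an N x 3
# matrix of parameter triples; computed in column chunks to bound memory.
.log_posterior_kernel_grid <- function(rec, prior, params, chunk = 20000L) {
  t_ <- rec$time
  ev <- rec$event == 1L
  lt <- log(t_)
  nev <- sum(ev)
  N <- nrow(params)
  out <- numeric(N)
  for (start in seq(1L, N, by = chunk)) {
    cols <- start:min(start + chunk - 1L, N)
    th <- params[cols, 1L]; sg <- params[cols, 2L]; mu <- params[cols, 3L]
    B <- outer(lt, log(th), `-`)                 # m x ncols: log(t_i / theta_j)
    Z <- exp(sweep(B, 2L, sg, `*`))              # (t_i / theta_j)^sigma_j
    ll <- nev * (log(sg) + log(mu)) +
      (sg - 1) * colSums(B[ev, , drop = FALSE]) +
      colSums(Z[ev, , drop = FALSE]) -
      mu * th * colSums(expm1(Z))
    ll[!is.finite(ll)] <- -Inf
    out[cols] <- ll + colSums((prior$shapes - 1) * t(log(params[cols, , drop = FALSE]))) -
      colSums(prior$rates * t(params[cols, , drop = FALSE]))
  }
  out
}
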