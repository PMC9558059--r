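#' Scalar functions of the parameters for posterior expectation
#'
#' The Lindley engine approximates \eqn{E[h(\Psi) | x]} for a smooth
#' scalar `h`; it needs `h`, its gradient and its Hessian evaluated at
#' the expansion point.  `h_function()` bundles those three;
#' `h_power()` and `h_log()` build the one-coordinate functions the
#' loss-function moments require (\eqn{\phi^k} and \eqn{\log\phi} for a
#' single parameter \eqn{\phi}), with analytic derivatives.
#'
#' @param value scalar, `h` at the expansion point.
#' @param gradient numeric 3-vector of first derivatives.
#' @param hessian symmetric 3x3 matrix of second derivatives.
#' @return An object of class `h_function`.
#' @export
h_function <- function(value, gradient, hessian) {
  gradient <- as.numeric(gradient)
  hessian <- as.matrix(hessian)
  stopifnot(length(value) == 1L, length(gradient) == 3L,
            all(dim(hessian) == c(3L, 3L)),
            max(abs(hessian - t(hessian))) < 1e-8)
  structure(list(value = as.numeric(value), gradient = gradient, hessian = hessian),
            class = "h_function")
}

#' @rdname h_function
#' @param coord which parameter (1 = theta, 2 = sigma, 3 = mu).
#' @param power exponent k of \eqn{\phi^k} (any nonzero real).
#' @param params expansion point, an [mwed_params()] triple.
#' @export
h_power <- function(coord, power, params) {
  p <- as.numeric(as_mwed_params(params))
  v <- p[coord]^power
  g <- numeric(3); g[coord] <- power * p[coord]^(power - 1)
  H <- matrix(0, 3, 3); H[coord, coord] <- power * (power - 1) * p[coord]^(power - 2)
  h_function(v, g, H)
}

#' @rdname h_function
#' @export
h_log <- function(coord, params) {
  p <- as.numeric(as_mwed_params(params))
  g <- numeric(3); g[coord] <- 1 / p[coord]
  H <- matrix(0, 3, 3); H[coord, coord] <- -1 / p[coord]^2
  h_function(log(p[coord]), g, H)
}

#' Three-parameter Lindley approximation of a posterior expectation
#'
#' Approximates the ratio of posterior integrals
#' \eqn{E[h | x] = \int h e^{\ell + G} / \int e^{\ell + G}}
#' by the standard second-order expansion around the MLE:
#' \deqn{E[h] \approx h(\hat\Psi) + \sum_t h_t a_t
#'   + \sum_{t<u} h_{tu} S_{tu} + \tfrac12 \sum_t h_{tt} S_{tt}
#'   + \tfrac12 \sum_t K_t W_t,}
#' with \eqn{a_t = \sum_j \rho_j S_{tj}},
#' \eqn{K_t = \sum_{u,v} S_{uv} L_{uvt}} and
#' \eqn{W_t = \sum_u h_u S_{tu}}, where \eqn{S = (-L'')^{-1}} is the
#' inverse observed information, \eqn{L_{uvt}} the third-derivative
#' tensor of the log-likelihood and \eqn{\rho} the log-prior gradient.
#' With a flat prior, vanishing third derivatives and linear `h` the
#' expansion returns `h` at the MLE exactly.
#'
#' @param h an [h_function()] evaluated at the bundle's expansion point.
#' @param bundle a [derivative_bundle()] from a converged MLE.
#' @return The approximate posterior expectation, a single number.
#' @seealso [posterior_expectation_quadrature()] for the deterministic
#'   numerical-integration oracle this expansion is validated against.
#' @export
lindley_expectation <- function(h, bundle) {
  stopifnot(inherits(h, "h_function"), inherits(bundle, "derivative_bundle"))
  S <- bundle$S
  a_vec <- as.numeric(S %*% bundle$rho)
  term_prior <- sum(h$gradient * a_vec)
  term_off <- sum(h$hessian[upper.tri(h$hessian)] * S[upper.tri(S)])
  term_diag <- 0.5 * sum(diag(h$hessian) * diag(S))
  K <- vapply(1:3, function(t) sum(S * bundle$third[, , t]), numeric(1))
  W <- as.numeric(S %*% h$gradient)
  h$value + term_prior + term_off + term_diag + 0.5 * sum(K * W)
}

#' Lindley-approximate posterior moments of each MWED parameter
#'
#' For every parameter \eqn{\phi \in \{\theta, \sigma, \mu\}} computes
#' the five posterior moments the loss-function estimators need:
#' \eqn{E[\phi]}, \eqn{E[\phi^2]}, \eqn{E[\phi^{-1}]},
#' \eqn{E[\phi^{-2}]} and \eqn{E[\log\phi]}.
#'
#' @param bundle a [derivative_bundle()].
#' @return A 3x5 numeric matrix; rows `theta`, `sigma`, `mu`, columns
#'   `m1`, `m2`, `minv1`, `minv2`, `mlog`.
#' @export
lindley_moments <- function(bundle) {
  p <- as_mwed_params(bundle$mle)
  out <- matrix(NA_real_, 3, 5,
                dimnames = list(c("theta", "sigma", "mu"),
                                c("m1", "m2", "minv1", "minv2", "mlog")))
  for (coord in 1:3) {
    out[coord, "m1"]    <- lindley_expectation(h_power(coord, 1, p), bundle)
    out[coord, "m2"]    <- lindley_expectation(h_power(coord, 2, p), bundle)
    out[coord, "minv1"] <- lindley_expectation(h_power(coord, -1, p), bundle)
    out[coord, "minv2"] <- lindley_expectation(h_power(coord, -2, p), bundle)
    out[coord, "mlog"]  <- lindley_expectation(h_log(coord, p), bundle)
  }
  out
}
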