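#' Log-likelihood derivative bundle for the Lindley approximation
#'
#' Evaluates, at a parameter point `params` (normally the MLE), every
#' derivative quantity the three-parameter Lindley expansion consumes:
#' the Hessian \eqn{L_{tu}} of the censored log-likelihood, the third
#' derivative tensor \eqn{L_{tuk}}, the inverse information matrix
#' \eqn{S = (-L_{tu})^{-1}}, and the log-prior gradient `rho`
#' (\eqn{A_t}).
#'
#' Derivatives are built from the analytic gradient
#' ([loglik_rc_grad()]): the Hessian by Richardson-extrapolated central
#' differences with relative step \eqn{\epsilon^{1/3} |p_t|}, the third
#' tensor by a nested four-point central-difference scheme with the
#' larger relative step \eqn{\epsilon^{1/5} |p_t|} (two stacked
#' differences amplify roundoff, so a larger step is needed); both are
#' exact for cubic log-likelihoods up to roundoff.  Results are
#' symmetrized over index permutations.
#'
#' @param d a [censored_sample()] or [survival_records()] object.
#' @param params point of evaluation, an [mwed_params()] triple.
#' @param prior_gradient log-prior gradient \eqn{A_t} at `params`
#'   (see [log_prior_gradient()]); `c(0,0,0)` is the flat-prior limit.
#' @return A list of class `derivative_bundle` with elements `mle`,
#'   `hessian` (3x3), `third` (3x3x3), `S` (3x3), `rho`.
#' @details If the negative Hessian is not positive definite the
#'   function throws an error of class `mwed_information_error`
#'   ("information matrix not PD"); the Monte-Carlo study drops such
#'   replicates.
#' @seealso [numeric_derivative_bundle()] for the same construction on
#'   an arbitrary gradient function (used to validate the scheme on
#'   polynomial test functions).
#' @export
derivative_bundle <- function(d, params, prior_gradient = c(0, 0, 0)) {
  rec <- as_survival_records(d)
  p <- as_mwed_params(params)
  grad_fn <- .loglik_closures(rec)$gr
  numeric_derivative_bundle(grad_fn, as.numeric(p), rho = prior_gradient, mle = p)
}

#' Derivative bundle from an arbitrary gradient function
#'
#' The finite-difference machinery behind [derivative_bundle()],
#' exposed so its accuracy can be validated on functions with known
#' derivatives (quadratics, cubics).
#'
#' @param grad_fn function mapping a numeric 3-vector to the gradient
#'   3-vector of the objective.
#' @param at numeric 3-vector, point of evaluation.
#' @param rho log-prior gradient to store in the bundle.
#' @param mle optional [mwed_params()] to store as the expansion point.
#' @return Same structure as [derivative_bundle()].
#' @export
numeric_derivative_bundle <- function(grad_fn, at, rho = c(0, 0, 0), mle = NULL) {
  at <- as.numeric(at)
  stopifnot(length(at) == 3L)

  # Hessian: Richardson-extrapolated central differences of the gradient.
  # Steps are proportional to |p| (the parameters are positive scales and
  # can sit orders of magnitude below 1, where an absolute step would
  # cross zero).
  h2 <- .Machine$double.eps^(1 / 3) * abs(at)
  H <- matrix(0, 3, 3)
  for (u in 1:3) {
    e <- numeric(3); e[u] <- 1
    d1 <- (grad_fn(at + h2[u] * e) - grad_fn(at - h2[u] * e)) / (2 * h2[u])
    d2 <- (grad_fn(at + h2[u] / 2 * e) - grad_fn(at - h2[u] / 2 * e)) / h2[u]
    H[, u] <- (4 * d2 - d1) / 3
  }
  H <- (H + t(H)) / 2

  # Third tensor: T[t,u,k] = d^2 g_t / dp_u dp_k by the 4-point formula
  h3 <- .Machine$double.eps^(1 / 5) * abs(at)
  T3 <- array(0, c(3, 3, 3))
  for (u in 1:3) {
    eu <- numeric(3); eu[u] <- 1
    for (k in u:3) {
      ek <- numeric(3); ek[k] <- 1
      gpp <- grad_fn(at + h3[u] * eu + h3[k] * ek)
      gpm <- grad_fn(at + h3[u] * eu - h3[k] * ek)
      gmp <- grad_fn(at - h3[u] * eu + h3[k] * ek)
      gmm <- grad_fn(at - h3[u] * eu - h3[k] * ek)
      T3[, u, k] <- (gpp - gpm - gmp + gmm) / (4 * h3[u] * h3[k])
      T3[, k, u] <- T3[, u, k]
    }
  }
  # symmetrize over all index permutations: one canonical average per
  # sorted index triple, assigned to every permutation (bit-identical
  # entries under index exchange)
  Ts <- array(0, c(3, 3, 3))
  for (t in 1:3) for (u in t:3) for (k in u:3) {
    v <- (T3[t, u, k] + T3[u, t, k] + T3[k, u, t] +
          T3[t, k, u] + T3[u, k, t] + T3[k, t, u]) / 6
    for (perm in list(c(t, u, k), c(u, t, k), c(k, u, t),
                      c(t, k, u), c(u, k, t), c(k, t, u))) {
      Ts[perm[1], perm[2], perm[3]] <- v
    }
  }

  info <- -H
  ev <- eigen(info, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop(structure(class = c("mwed_information_error", "error", "condition"),
                   list(message = "information matrix not PD at the expansion point",
                        call = sys.call(-1))))
  }
  S <- chol2inv(chol(info))
  S <- (S + t(S)) / 2

  structure(list(mle = if (is.null(mle)) at else mle,
                 hessian = H, third = Ts, S = S, rho = as.numeric(rho)),
            class = "derivative_bundle")
}
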