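#' Bayes estimators and posterior risks under four loss functions
#'
#' Given the posterior moments of a positive scalar parameter
#' \eqn{\phi}, returns the Bayes estimator and posterior risk under:
#' \describe{
#'   \item{SELF}{squared-error loss: estimate \eqn{E[\phi]},
#'     risk \eqn{E[\phi^2] - E[\phi]^2}.}
#'   \item{PLF}{precautionary loss: estimate \eqn{\sqrt{E[\phi^2]}},
#'     risk \eqn{2(\sqrt{E[\phi^2]} - E[\phi])}.}
#'   \item{QLF}{quadratic loss: estimate \eqn{E[\phi^{-1}]/E[\phi^{-2}]},
#'     risk \eqn{1 - E[\phi^{-1}]^2/E[\phi^{-2}]}.}
#'   \item{ELF}{entropy loss: estimate \eqn{1/E[\phi^{-1}]},
#'     risk \eqn{E[\log\phi] + \log E[\phi^{-1}]}.}
#' }
#' For moments of a genuine posterior distribution the estimates are
#' ordered \eqn{QLF \le ELF \le SELF \le PLF} (Cauchy-Schwarz and
#' Jensen) and every risk is nonnegative with the QLF risk in [0, 1].
#' Moments produced by the Lindley expansion at small n can violate
#' these coherence conditions; in that case the estimates are still
#' returned but `risk_valid` is set to `FALSE` — nothing is clipped
#' silently.
#'
#' @param moments named numeric vector (or 1-row slice of
#'   [lindley_moments()]) with elements `m1` = \eqn{E[\phi]},
#'   `m2` = \eqn{E[\phi^2]}, `minv1` = \eqn{E[\phi^{-1}]},
#'   `minv2` = \eqn{E[\phi^{-2}]}, `mlog` = \eqn{E[\log\phi]}.
#' @return A data frame with one row per loss (`SELF`, `PLF`, `QLF`,
#'   `ELF`) and columns `loss`, `estimate`, `posterior_risk`,
#'   `risk_valid`.
#' @examples
#' # Gamma(shape 3, rate 2) posterior: closed-form moments
#' m <- c(m1 = 1.5, m2 = 3, minv1 = 1, minv2 = 2, mlog = digamma(3) - log(2))
#' estimator_from_moments(m)
#' @export
estimator_from_moments <- function(moments) {
  m <- moments[c("m1", "m2", "minv1", "minv2", "mlog")]
  if (anyNA(m) || any(!is.finite(m))) {
    stop("all five posterior moments must be finite", call. = FALSE)
  }
  m1 <- m[["m1"]]; m2 <- m[["m2"]]
  minv1 <- m[["minv1"]]; minv2 <- m[["minv2"]]; mlog <- m[["mlog"]]

  est <- c(SELF = m1,
           PLF  = sqrt(max(m2, 0)),
           QLF  = minv1 / minv2,
           ELF  = 1 / minv1)
  risk <- c(SELF = m2 - m1^2,
            PLF  = 2 * (sqrt(max(m2, 0)) - m1),
            QLF  = 1 - minv1^2 / minv2,
            ELF  = mlog + log(minv1))
  valid <- c(SELF = m2 >= m1^2,
             PLF  = m2 >= 0 && sqrt(m2) >= m1,
             QLF  = minv2 >= minv1^2 && minv2 > 0,
             ELF  = minv1 > 0 && (mlog + log(minv1)) >= 0)

  data.frame(loss = names(est), estimate = unname(est),
             posterior_risk = unname(risk), risk_valid = unname(valid),
             row.names = NULL)
}

#' Bayes estimates of all MWED parameters under all four losses
#'
#' Fits the MLE, forms the [derivative_bundle()] with the log-prior
#' gradient of `prior`, computes the five Lindley posterior moments of
#' each parameter and converts them into loss-function estimates and
#' posterior risks.  Setting `method = "quadrature"` replaces the
#' Lindley moments with deterministic 3-D quadrature
#' ([posterior_moments_quadrature()]) — slower, but immune to the
#' moment-incoherence the expansion can show at very small n.
#'
#' @param d a [censored_sample()] or [survival_records()] object.
#' @param prior a [gamma_prior()]; default flat.
#' @param method `"auto"` (Lindley for interior MLEs, quadrature when
#'   the fit sits at the Weibull-limit cap, where the expansion's
#'   inverse-information input degenerates), `"lindley"` or
#'   `"quadrature"`.
#' @param fit an optional pre-computed [fit_mwed_mle()] result for `d`.
#' @return A data frame with columns `parameter`, `loss`, `estimate`,
#'   `posterior_risk`, `risk_valid`; the MLE fit is attached as
#'   attribute `"mle"`.
#' @examples
#' x <- rmwed(120, 1, 1, 1, seed = 3)
#' s <- censored_sample(sort(x)[1:96], n = 120)
#' est <- bayes_estimates(s, elicit_gamma_prior(c(1, 1, 1)))
#' subset(est, parameter == "theta")
#' @export
bayes_estimates <- function(d, prior = flat_prior(),
                            method = c("auto", "lindley", "quadrature"),
                            fit = NULL) {
  method <- match.arg(method)
  if (is.null(fit)) fit <- fit_mwed_mle(d)
  if (method == "auto") method <- if (fit$boundary) "quadrature" else "lindley"
  if (method == "lindley") {
    rho <- log_prior_gradient(fit$params, prior)
    bundle <- derivative_bundle(d, fit$params, prior_gradient = rho)
    mom <- lindley_moments(bundle)
  } else {
    mom <- posterior_moments_quadrature(d, prior, fit = fit)
  }
  rows <- lapply(rownames(mom), function(par) {
    res <- estimator_from_moments(mom[par, ])
    cbind(parameter = par, res)
  })
  out <- do.call(rbind, rows)
  attr(out, "mle") <- fit
  attr(out, "moments") <- mom
  out
}
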