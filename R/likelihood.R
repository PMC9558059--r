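#' Censored-data log-likelihoods for the MWED
#'
#' `loglik_type2()` is the log of the type-II censored likelihood
#' \deqn{L = \prod_{i=1}^{r} f(x_{(i)}) \, [1 - F(x_{(r)})]^{n-r},}
#' where the survivor factor carries the full exponent
#' \eqn{(x_{(r)}/\theta)^\sigma}.  `loglik_rc()` is the general
#' right-censored log-likelihood
#' \eqn{\sum_{\mathrm{events}} \log f(t_i) +
#'   \sum_{\mathrm{censored}} \log R(t_i)},
#' needed when censoring times are interspersed among failures.
#' With `r = n` (no censoring) `loglik_type2()` reduces to the complete
#' log-likelihood \eqn{\sum \log f(x_i)}, and a type-II sample expanded
#' via [as_survival_records()] gives identical values under both
#' functions.
#'
#' Parameter regions where the likelihood overflows evaluate to `-Inf`,
#' which optimizers treat as infeasible.
#'
#' @param s a [censored_sample()].
#' @param d a [survival_records()] object (or anything
#'   [as_survival_records()] accepts).
#' @param params an [mwed_params()] triple (or numeric length-3 vector).
#' @return A single (possibly `-Inf`) numeric value; `loglik_rc_grad()`
#'   returns the analytic gradient, a numeric 3-vector d loglik /
#'   d(theta, sigma, mu).
#' @examples
#' s <- censored_sample(c(0.5, 1), n = 3)
#' loglik_type2(s, mwed_params(1, 1, 1))  # 4.5 - exp(0.5) - 2*exp(1)
#' @export
loglik_type2 <- function(s, params) {
  stopifnot(inherits(s, "censored_sample"))
  p <- as_mwed_params(params)
  theta <- p[["theta"]]; sigma <- p[["sigma"]]; mu <- p[["mu"]]
  x <- s$observed
  z <- (x / theta)^sigma
  ll <- s$r * (log(sigma) + log(mu)) +
    sum((sigma - 1) * log(x / theta) + z - mu * theta * expm1(z)) -
    (s$n - s$r) * mu * theta * expm1((s$x_r / theta)^sigma)
  if (!is.finite(ll)) -Inf else ll
}

#' @rdname loglik_type2
#' @export
loglik_rc <- function(d, params) {
  d <- as_survival_records(d)
  p <- as_mwed_params(params)
  theta <- p[["theta"]]; sigma <- p[["sigma"]]; mu <- p[["mu"]]
  z <- (d$time / theta)^sigma
  ev <- d$event == 1L
  ll <- sum(ev) * (log(sigma) + log(mu)) +
    sum((sigma - 1) * log(d$time[ev] / theta) + z[ev]) -
    mu * theta * sum(expm1(z))
  if (!is.finite(ll)) -Inf else ll
}

# Lean closures over the data vectors for optimizer/derivative hot loops:
# no class dispatch, no validation.  Returns list(ll, gr), both taking a
# bare numeric 3-vector (theta, sigma, mu).
.loglik_closures <- function(rec) {
  t_ <- rec$time
  ev <- rec$event == 1L
  te <- t_[ev]
  nev <- sum(ev)
  lt <- log(t_)
  lte <- lt[ev]
  list(
    ll = function(p) {
      z <- exp(p[2L] * (lt - log(p[1L])))
      ll <- nev * (log(p[2L]) + log(p[3L])) +
        sum((p[2L] - 1) * (lte - log(p[1L])) + z[ev]) -
        p[3L] * p[1L] * sum(expm1(z))
      if (is.finite(ll)) ll else -Inf
    },
    gr = function(p) {
      z <- exp(p[2L] * (lt - log(p[1L])))
      ez <- exp(z)
      ltc <- lt - log(p[1L])
      c(-sum(p[2L] - 1 + p[2L] * z[ev]) / p[1L] +
          p[3L] * sum(-expm1(z) + p[2L] * z * ez),
        nev / p[2L] + sum(ltc[ev] * (1 + z[ev])) -
          p[3L] * p[1L] * sum(z * ltc * ez),
        nev / p[3L] - p[1L] * sum(expm1(z)))
    }
  )
}

#' @rdname loglik_type2
#' @export
loglik_rc_grad <- function(d, params) {
  d <- as_survival_records(d)
  p <- as_mwed_params(params)
  theta <- p[["theta"]]; sigma <- p[["sigma"]]; mu <- p[["mu"]]
  t_ <- d$time
  ev <- d$event == 1L
  lt <- log(t_ / theta)
  z <- (t_ / theta)^sigma
  ez <- exp(z)
  g_theta <- -sum(sigma - 1 + sigma * z[ev]) / theta +
    mu * sum(-expm1(z) + sigma * z * ez)
  g_sigma <- sum(ev) / sigma + sum(lt[ev] * (1 + z[ev])) -
    mu * theta * sum(z * lt * ez)
  g_mu <- sum(ev) / mu - theta * sum(expm1(z))
  c(theta = g_theta, sigma = g_sigma, mu = g_mu)
}
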