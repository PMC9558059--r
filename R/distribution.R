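#' The Modified Weibull Extension distribution
#'
#' Density, distribution function, reliability (survival) function,
#' hazard rate, quantile function and random generation for the
#' three-parameter Modified Weibull Extension distribution (MWED) with
#' scale `theta` and shapes `sigma`, `mu`.
#'
#' The density is
#' \deqn{f(x) = \sigma\mu (x/\theta)^{\sigma-1}
#'   \exp\!\left[(x/\theta)^\sigma +
#'   \mu\theta\{1 - e^{(x/\theta)^\sigma}\}\right], \quad x \ge 0,}
#' with distribution function
#' \deqn{F(x) = 1 - \exp\!\left[\mu\theta\{1 - e^{(x/\theta)^\sigma}\}\right].}
#' The cumulative hazard is \eqn{H(x) = \mu\theta(e^{(x/\theta)^\sigma} - 1)},
#' so the hazard rate is
#' \eqn{r(x) = \sigma\mu(x/\theta)^{\sigma-1} e^{(x/\theta)^\sigma}};
#' it is increasing for \eqn{\sigma \ge 1} and bathtub-shaped for
#' \eqn{\sigma < 1}.  The quantile function is the analytic inverse of
#' \eqn{F}:
#' \deqn{Q(u) = \theta\left[\log\!\left(1 -
#'   \frac{\log(1-u)}{\mu\theta}\right)\right]^{1/\sigma}.}
#'
#' Numerics: the exponent \eqn{\mu\theta(1 - e^{z})} with
#' \eqn{z = (x/\theta)^\sigma} is evaluated with `expm1()`; once it falls
#' below about -745 the cdf saturates at 1 (reliability at 0) in double
#' precision.  At `x = 0` the density is defined by continuity: 0 when
#' `sigma > 1`, `sigma * mu` when `sigma = 1`, and `Inf` when `sigma < 1`.
#'
#' @param x,q vector of nonnegative quantiles (times); `x > 0` required
#'   for `hmwed`.
#' @param p vector of probabilities in (0, 1).
#' @param n number of random draws.
#' @param theta,sigma,mu strictly positive MWED parameters; see
#'   [mwed_params()].
#' @param log,log.p logical; if `TRUE`, probabilities/densities are
#'   returned on the log scale.
#' @param lower.tail logical; if `TRUE` (default), probabilities are
#'   \eqn{P(X \le x)}, otherwise \eqn{P(X > x)}.
#' @param seed optional integer; if supplied, `rmwed` draws with this
#'   seed using a local RNG state (the caller's RNG stream is untouched).
#' @return `dmwed` the density, `pmwed` the distribution function,
#'   `smwed` the reliability \eqn{R(x) = 1 - F(x)}, `hmwed` the hazard
#'   rate, `qmwed` the quantile function, `rmwed` a vector of `n`
#'   positive variates drawn by inverse-transform sampling.
#' @examples
#' dmwed(1, 1, 1, 1)            # exp(2 - e)
#' pmwed(log(2), 1, 1, 1)       # 1 - exp(-1)
#' qmwed(1 - exp(-1), 1, 1, 1)  # log(2)
#' x <- rmwed(5, 1, 2, 0.5, seed = 7)
#' @name mwed
NULL

.check_mwed_args <- function(theta, sigma, mu) {
  mwed_params(theta, sigma, mu)
  invisible(NULL)
}

# exponent of the survival function: mu*theta*(1 - exp(z)), z = (x/theta)^sigma
.mwed_log_surv <- function(x, theta, sigma, mu) {
  z <- (x / theta)^sigma
  -mu * theta * expm1(z)
}

#' @rdname mwed
#' @export
dmwed <- function(x, theta, sigma, mu, log = FALSE) {
  .check_mwed_args(theta, sigma, mu)
  if (any(x < 0, na.rm = TRUE)) stop("x must be nonnegative", call. = FALSE)
  z <- (x / theta)^sigma
  logf <- log(sigma) + log(mu) + (sigma - 1) * log(x / theta) +
    z - mu * theta * expm1(z)
  # x = 0 by continuity
  at0 <- which(x == 0)
  if (length(at0)) {
    logf[at0] <- if (sigma > 1) -Inf else if (sigma == 1) log(sigma * mu) else Inf
  }
  if (log) logf else exp(logf)
}

#' @rdname mwed
#' @export
pmwed <- function(q, theta, sigma, mu, lower.tail = TRUE, log.p = FALSE) {
  .check_mwed_args(theta, sigma, mu)
  if (any(q < 0, na.rm = TRUE)) stop("q must be nonnegative", call. = FALSE)
  ls <- .mwed_log_surv(q, theta, sigma, mu)
  if (lower.tail) {
    p <- -expm1(ls)
    if (log.p) log(p) else p
  } else {
    if (log.p) ls else exp(ls)
  }
}

#' @rdname mwed
#' @export
smwed <- function(x, theta, sigma, mu) {
  pmwed(x, theta, sigma, mu, lower.tail = FALSE)
}

#' @rdname mwed
#' @export
hmwed <- function(x, theta, sigma, mu) {
  .check_mwed_args(theta, sigma, mu)
  if (any(x <= 0, na.rm = TRUE)) stop("hazard requires x > 0", call. = FALSE)
  z <- (x / theta)^sigma
  sigma * mu * (x / theta)^(sigma - 1) * exp(z)
}

#' @rdname mwed
#' @export
qmwed <- function(p, theta, sigma, mu, lower.tail = TRUE, log.p = FALSE) {
  .check_mwed_args(theta, sigma, mu)
  if (log.p) p <- exp(p)
  if (!lower.tail) p <- 1 - p
  if (any(p <= 0 | p >= 1, na.rm = TRUE)) {
    stop("probabilities must lie strictly inside (0, 1)", call. = FALSE)
  }
  # invert 1 - exp(mu*theta*(1 - e^z)): e^z = 1 - log(1-p)/(mu*theta)
  theta * (log1p(-log1p(-p) / (mu * theta)))^(1 / sigma)
}

#' @rdname mwed
#' @export
rmwed <- function(n, theta, sigma, mu, seed = NULL) {
  .check_mwed_args(theta, sigma, mu)
  if (!is.null(seed)) {
    u <- with_local_seed(seed, stats::runif(n))
  } else {
    u <- stats::runif(n)
  }
  qmwed(u, theta, sigma, mu)
}

# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_local_seed <- function(seed, expr) {
  seed <- as.integer(seed %% .Machine$integer.max)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
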