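#' Maximum-likelihood fit of the MWED to right-censored data
#'
#' Maximizes the censored log-likelihood ([loglik_type2()] /
#' [loglik_rc()]) over (theta, sigma, mu).  The optimization runs in
#' log-parameter space, which enforces positivity without box
#' constraints, using BFGS with the analytic gradient followed by a
#' Newton polish.  Because the likelihood surface can be multimodal for
#' small censored samples, a deterministic multi-start is used: the 8
#' combinations of \{0.5x, 2x\} around a moment-style initial guess
#' (theta0 = sample median, sigma0 = 1, mu0 = 1/theta0), plus the
#' all-ones point; the start with the best final log-likelihood wins.
#'
#' @section The Weibull boundary:
#' As theta grows with `mu * theta^(1 - sigma)` held fixed the MWED
#' degenerates to a two-parameter Weibull, and for samples whose upper
#' tail carries no curvature information the likelihood increases
#' monotonically toward that limit — the MLE then does not exist in the
#' interior.  The estimator is therefore defined on the compactified
#' space `theta <= theta_max` (default `10 * max(t)`: beyond ten times
#' the largest observation the MWED is indistinguishable from its
#' limiting Weibull at the observed times).  When the optimum attains
#' the cap, theta is fixed there, the remaining two parameters are
#' re-maximized (a profile fit of the near-Weibull limit) and the
#' result is flagged `boundary = TRUE`; the Monte-Carlo study drops
#' such replicates as non-identified, while dataset fitting reports
#' them.
#'
#' @param d a [censored_sample()] or [survival_records()] object.
#' @param theta_max cap on the scale parameter; default `10 * max(t)`.
#' @param grad_tol stationarity tolerance for interior fits: converged
#'   when every gradient component satisfies
#'   `|g| <= grad_tol * (1 + |loglik|)`.
#' @param maxit maximum BFGS iterations per start.
#' @return A list of class `mwed_mle` with elements `params`
#'   ([mwed_params()]), `loglik`, `gradient` (natural scale),
#'   `converged` (logical), `boundary` (logical: `TRUE` when theta sits
#'   at `theta_max`), and `starts_tried`.
#' @details If no interior start reaches the stationarity tolerance and
#'   the boundary profile also fails, an error of class
#'   `mwed_convergence_error` is thrown; its `best` field carries the
#'   best point found, so callers (e.g. the Monte-Carlo study) can drop
#'   the replicate and log it.
#' @examples
#' x <- rmwed(200, 1, 1, 1, seed = 42)
#' s <- censored_sample(sort(x)[1:160], n = 200)
#' fit <- fit_mwed_mle(s)
#' fit$params
#' @export
fit_mwed_mle <- function(d, theta_max = NULL, grad_tol = 1e-6, maxit = 500L) {
  rec <- as_survival_records(d)
  cl <- .loglik_closures(rec)
  if (is.null(theta_max)) theta_max <- 10 * max(rec$time)

  negll <- function(lp) {
    ll <- cl$ll(exp(lp))
    if (!is.finite(ll)) return(1e300)
    -ll
  }
  neggr <- function(lp) {
    p <- exp(lp)
    g <- cl$gr(p)
    if (any(!is.finite(g))) return(rep(0, 3))  # paired with the 1e300 barrier
    -g * p                                     # chain rule d/d log p
  }

  theta0 <- stats::median(rec$time)
  guess <- c(theta0, 1, 1 / theta0)
  mults <- as.matrix(expand.grid(c(0.5, 2), c(0.5, 2), c(0.5, 2)))
  starts <- rbind(sweep(mults, 2L, guess, `*`), c(1, 1, 1))

  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(log(starts[k, ]), fn = negll, gr = neggr, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-14)),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop(structure(class = c("mwed_convergence_error", "error", "condition"),
                   list(message = "MLE failed: no start produced a finite log-likelihood",
                        call = sys.call(-1), best = NULL)))
  }

  # Newton polish in log space: BFGS can stall short of stationarity on
  # the flat ridges this likelihood develops.
  lp <- best$par
  ll <- -best$value
  for (it in 1:25) {
    p <- exp(lp)
    if (p[1L] > theta_max) break
    g_nat <- cl$gr(p)
    if (all(abs(g_nat) <= 0.01 * grad_tol * (1 + abs(ll)))) break
    H_log <- .log_space_hessian(cl$gr, lp)
    step <- tryCatch(solve(-H_log, g_nat * p), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lam <- 1
    improved <- FALSE
    for (half in 1:20) {          # backtracking on the log-likelihood
      cand <- lp + lam * step
      ll_cand <- cl$ll(exp(cand))
      if (is.finite(ll_cand) && ll_cand >= ll) {
        lp <- cand; ll <- ll_cand; improved <- TRUE; break
      }
      lam <- lam / 2
    }
    if (!improved) break
  }

  boundary <- exp(lp)[1L] >= theta_max
  if (boundary) {
    # profile fit of the near-Weibull limit: theta pinned at the cap
    lth <- log(theta_max)
    o2 <- stats::optim(pmin(pmax(lp[2:3], -30), 30), function(lq) {
      ll2 <- cl$ll(c(theta_max, exp(lq)))
      if (!is.finite(ll2)) 1e300 else -ll2
    }, method = "Nelder-Mead", control = list(maxit = 2000L, reltol = 1e-13))
    lp <- c(lth, o2$par)
    ll <- -o2$value
  }

  p_hat <- exp(lp)
  g <- loglik_rc_grad(rec, p_hat)
  converged <- boundary || all(abs(g) <= grad_tol * (1 + abs(ll)))
  out <- list(params = mwed_params(p_hat[1], p_hat[2], p_hat[3]),
              loglik = ll,
              gradient = g,
              converged = converged,
              boundary = boundary,
              starts_tried = nrow(starts))
  class(out) <- "mwed_mle"
  if (!converged) {
    stop(structure(class = c("mwed_convergence_error", "error", "condition"),
                   list(message = sprintf(
                     "MLE did not reach stationarity (max scaled |gradient| = %.3g)",
                     max(abs(g)) / (1 + abs(ll))),
                     call = sys.call(-1), best = out)))
  }
  out
}

# central-difference Hessian of the log-likelihood w.r.t. log-parameters
.log_space_hessian <- function(gr_nat, lp) {
  h <- .Machine$double.eps^(1 / 3)
  H <- matrix(0, 3, 3)
  for (u in 1:3) {
    e <- numeric(3); e[u] <- 1
    gp <- gr_nat(exp(lp + h * e)) * exp(lp + h * e)
    gm <- gr_nat(exp(lp - h * e)) * exp(lp - h * e)
    H[, u] <- (gp - gm) / (2 * h)
  }
  (H + t(H)) / 2
}

#' @export
print.mwed_mle <- function(x, ...) {
  cat("MWED maximum-likelihood fit\n")
  print(x$params)
  cat(sprintf("log-likelihood: %.6g (converged: %s%s)\n", x$loglik, x$converged,
              if (x$boundary) "; theta at the Weibull-limit cap" else ""))
  invisible(x)
}
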