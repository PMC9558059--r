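#' Configuration of a Monte-Carlo estimator-comparison study
#'
#' Describes one cell of the simulation protocol: generate type-II
#' right-censored MWED samples at a known truth, estimate by maximum
#' likelihood and by the four Bayes rules (gamma priors centred at the
#' truth), and aggregate means and mean squared errors over replicates.
#'
#' @param truth true parameter triple, an [mwed_params()] or numeric
#'   3-vector.
#' @param n sample size (items on test).
#' @param censoring_fraction fraction censored; `r = round(n * (1 -
#'   censoring_fraction))` items are observed.  Default 0.20.
#' @param replicates number of Monte-Carlo replicates (default 10000;
#'   scale down for desk-scale runs).
#' @param prior_rates gamma prior rates `b_t` (scalar or 3-vector); the
#'   shapes are elicited so the prior means equal `truth`.
#' @param seed master seed; replicate `k` uses `seed + k`, so any
#'   replicate is reproducible in isolation.
#' @param methods subset of `c("mle", "bayes")`.
#' @param max_drop_fraction abort threshold: the study errors when more
#'   than this fraction of replicates is dropped (non-convergent,
#'   boundary, non-PD information or incoherent expansion moments).
#'   The default 0.2 treats heavier losses as a sign the model is too
#'   weakly identified at the configuration; raise it deliberately to
#'   study such regimes, in which case the drop accounting attached to
#'   the result is part of the answer.
#' @return A list of class `study_config`.
#' @export
study_config <- function(truth, n, censoring_fraction = 0.20, replicates = 10000L,
                         prior_rates = 1, seed = 1L,
                         methods = c("mle", "bayes"),
                         max_drop_fraction = 0.2) {
  truth <- as_mwed_params(truth)
  n <- as.integer(n)
  r <- as.integer(round(n * (1 - censoring_fraction)))
  if (censoring_fraction < 0 || censoring_fraction >= 1 || r < 3L) {
    stop("censoring_fraction must lie in [0, 1) and leave r >= 3 observed failures",
         call. = FALSE)
  }
  methods <- match.arg(methods, several.ok = TRUE)
  structure(list(truth = truth, n = n, r = r,
                 censoring_fraction = censoring_fraction,
                 replicates = as.integer(replicates),
                 prior_rates = rep_len(as.numeric(prior_rates), 3L),
                 seed = as.integer(seed), methods = methods,
                 max_drop_fraction = max_drop_fraction),
            class = "study_config")
}

#' Generate one type-II right-censored MWED sample
#'
#' Draws `n` variates by inverse-transform sampling, sorts them
#' ascending and keeps the first `r` order statistics; the `r`-th is
#' the termination time.
#'
#' @param n items on test.
#' @param r number of observed failures, `1 <= r <= n`.
#' @param truth an [mwed_params()] triple.
#' @param seed optional integer seed for the draw.
#' @return A [censored_sample()].
#' @examples
#' generate_censored_sample(20, 16, mwed_params(1, 1, 1), seed = 1)
#' @export
generate_censored_sample <- function(n, r, truth, seed = NULL) {
  truth <- as_mwed_params(truth)
  if (r < 1L || r > n) stop("need 1 <= r <= n", call. = FALSE)
  x <- sort(rmwed(n, truth[["theta"]], truth[["sigma"]], truth[["mu"]], seed = seed))
  censored_sample(x[seq_len(r)], n = n)
}

#' Monte-Carlo mean squared error about the true value
#'
#' @param estimates nonempty numeric vector of estimates.
#' @param truth the true scalar value.
#' @return `mean((estimates - truth)^2)`.
#' @export
mse <- function(estimates, truth) {
  if (length(estimates) == 0L) stop("no estimates supplied", call. = FALSE)
  mean((estimates - truth)^2)
}

#' Run a Monte-Carlo estimator-comparison study
#'
#' Per replicate: a fresh seeded type-II censored sample is generated
#' ([generate_censored_sample()]), the MLE fitted, and — when `"bayes"`
#' is among the configured methods — the four loss-function Bayes
#' estimates computed via the Lindley expansion with gamma priors whose
#' means equal the true values.  Replicates where the MLE fails to
#' converge or the observed information is not positive definite are
#' dropped and counted; more than 20% drops aborts the study.
#'
#' @param cfg a [study_config()].
#' @param progress if `TRUE`, prints one line per 100-replicate batch.
#' @return A data frame of class `study_result` with columns `n`,
#'   `parameter`, `method`, `mean`, `mse`, plus attributes `dropped`,
#'   `kept` and `config`.  Identical configs give bit-identical
#'   results.
#' @examples
#' cfg <- study_config(c(1, 1, 1), n = 20, replicates = 25, seed = 7,
#'                     methods = "mle")
#' run_study(cfg)
#' @export
run_study <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "study_config"))
  truth <- as.numeric(cfg$truth)
  do_bayes <- "bayes" %in% cfg$methods
  prior <- elicit_gamma_prior(truth, cfg$prior_rates)
  methods <- c(if ("mle" %in% cfg$methods) "MLE",
               if (do_bayes) c("SELF", "PLF", "QLF", "ELF"))
  pnames <- c("theta", "sigma", "mu")

  est <- array(NA_real_, c(cfg$replicates, length(methods), 3L),
               dimnames = list(NULL, methods, pnames))
  drop_reason <- c(nonconvergence = 0L, boundary = 0L, information_not_pd = 0L,
                   incoherent_moments = 0L)
  for (k in seq_len(cfg$replicates)) {
    s <- generate_censored_sample(cfg$n, cfg$r, cfg$truth, seed = cfg$seed + k)
    reason <- tryCatch({
      fit <- fit_mwed_mle(s)
      if (fit$boundary) stop(structure(
        class = c("mwed_boundary", "error", "condition"),
        list(message = "boundary", call = NULL)))
      # the inverse information must exist for every reported method
      # (the Lindley expansion consumes it; for the MLE it is the
      # existence check of a proper interior maximum)
      rho <- if (do_bayes) log_prior_gradient(fit$params, prior) else c(0, 0, 0)
      bundle <- derivative_bundle(s, fit$params, prior_gradient = rho)
      if ("MLE" %in% methods) est[k, "MLE", ] <- as.numeric(fit$params)
      if (do_bayes) {
        mom <- lindley_moments(bundle)
        # the expansion can return unusable moments (non-finite, or
        # negative for a positive parameter) when the information is
        # marginal; such replicates are dropped, never clipped
        if (any(!is.finite(mom)) || any(mom[, c("m1", "m2", "minv1", "minv2")] <= 0)) {
          stop(structure(class = c("mwed_moment_error", "error", "condition"),
                         list(message = "incoherent Lindley moments", call = NULL)))
        }
        for (par in 1:3) {
          e <- estimator_from_moments(mom[par, ])
          est[k, e$loss, par] <- e$estimate
        }
      }
      NULL
    },
    mwed_moment_error = function(e) "incoherent_moments",
    mwed_boundary = function(e) "boundary",
    mwed_convergence_error = function(e) "nonconvergence",
    mwed_information_error = function(e) "information_not_pd")
    if (!is.null(reason)) {
      drop_reason[reason] <- drop_reason[reason] + 1L
      est[k, , ] <- NA_real_
    }
    if (progress && k %% 100L == 0L) {
      message(sprintf("replicate %d / %d (%d dropped)", k, cfg$replicates,
                      sum(drop_reason)))
    }
  }
  dropped <- sum(drop_reason)
  if (dropped > cfg$max_drop_fraction * cfg$replicates) {
    stop(sprintf(
      "%d of %d replicates dropped (> %.0f%%; %s): the model is too weakly identified at this configuration",
      dropped, cfg$replicates, 100 * cfg$max_drop_fraction,
      paste(names(drop_reason), drop_reason, sep = "=", collapse = ", ")),
      call. = FALSE)
  }

  rows <- expand.grid(parameter = pnames, method = methods,
                      stringsAsFactors = FALSE)[, 2:1]
  rows$n <- cfg$n
  rows$mean <- NA_real_
  rows$mse <- NA_real_
  for (i in seq_len(nrow(rows))) {
    v <- est[, rows$method[i], rows$parameter[i]]
    v <- v[!is.na(v)]
    rows$mean[i] <- mean(v)
    rows$mse[i] <- mse(v, truth[match(rows$parameter[i], pnames)])
  }
  out <- rows[, c("n", "parameter", "method", "mean", "mse")]
  class(out) <- c("study_result", "data.frame")
  attr(out, "dropped") <- dropped
  attr(out, "drop_reason") <- drop_reason
  attr(out, "kept") <- cfg$replicates - dropped
  attr(out, "config") <- cfg
  out
}
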