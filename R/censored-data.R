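#' Type-II right-censored sample
#'
#' A life test places `n` items on test and stops at the `r`-th failure:
#' the observed data are the first `r` order statistics
#' \eqn{x_{(1)} \le \dots \le x_{(r)}}, and the remaining `n - r` items
#' are known only to have survived past \eqn{x_{(r)}}.
#'
#' @param observed numeric vector of the `r` observed failure times,
#'   sorted ascending (unsorted input is an error, not silently sorted:
#'   order statistics are part of the design).
#' @param n total number of items on test, `n >= length(observed)`.
#' @return An object of class `censored_sample` with fields `observed`,
#'   `n`, `r` and the termination time `x_r`.
#' @seealso [survival_records()] for general (interspersed) right
#'   censoring.
#' @examples
#' censored_sample(c(0.5, 1.0), n = 3)
#' @export
censored_sample <- function(observed, n) {
  observed <- as.numeric(observed)
  r <- length(observed)
  if (r < 1L) stop("need at least one observed failure", call. = FALSE)
  if (anyNA(observed) || any(observed <= 0) || any(!is.finite(observed))) {
    stop("observed failure times must be finite and strictly positive", call. = FALSE)
  }
  if (is.unsorted(observed)) {
    stop("observed must be sorted ascending (the first r order statistics)", call. = FALSE)
  }
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < r) {
    stop("n must be a single integer >= length(observed)", call. = FALSE)
  }
  structure(list(observed = observed, n = n, r = r, x_r = observed[r]),
            class = "censored_sample")
}

#' @export
print.censored_sample <- function(x, ...) {
  cat(sprintf("Type-II censored sample: n = %d items on test, r = %d failures observed, x_r = %g\n",
              x$n, x$r, x$x_r))
  invisible(x)
}

#' General right-censored survival records
#'
#' Pairs of a positive time and an event indicator (1 = failure
#' observed, 0 = right-censored).  Unlike [censored_sample()], censoring
#' times may be interspersed among the failures, as in clinical
#' follow-up data.
#'
#' @param time numeric vector of positive times.
#' @param event vector of 0/1 (or logical) event indicators, same
#'   length; at least one event is required.
#' @return An object of class `survival_records`: a data frame with
#'   columns `time` and `event`.
#' @examples
#' survival_records(c(5, 8, 12), c(1, 0, 1))
#' @export
survival_records <- function(time, event) {
  time <- as.numeric(time)
  event <- as.integer(event)
  if (length(time) != length(event)) {
    stop("time and event must have the same length", call. = FALSE)
  }
  if (anyNA(time) || any(!is.finite(time)) || any(time <= 0)) {
    stop("times must be finite and strictly positive", call. = FALSE)
  }
  if (anyNA(event) || !all(event %in% c(0L, 1L))) {
    stop("event indicators must be 0 (censored) or 1 (failure)", call. = FALSE)
  }
  if (!any(event == 1L)) stop("at least one observed event is required", call. = FALSE)
  structure(data.frame(time = time, event = event),
            class = c("survival_records", "data.frame"))
}

#' @export
print.survival_records <- function(x, ...) {
  cat(sprintf("Right-censored survival records: %d observations, %d events, %d censored\n",
              nrow(x), sum(x$event == 1L), sum(x$event == 0L)))
  NextMethod()
}

#' Expand a type-II sample into general survival records
#'
#' The `n - r` unfailed items become censored records at the
#' termination time `x_r`.
#'
#' @param s a [censored_sample()].
#' @return A [survival_records()] object with `n` rows.
#' @export
as_survival_records <- function(s) {
  if (inherits(s, "survival_records")) return(s)
  stopifnot(inherits(s, "censored_sample"))
  survival_records(
    time = c(s$observed, rep(s$x_r, s$n - s$r)),
    event = c(rep(1L, s$r), rep(0L, s$n - s$r))
  )
}
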