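#' Parameter triple of the Modified Weibull Extension distribution
#'
#' Constructs and validates the three-parameter set of the MWED:
#' a scale `theta` (same units as the time variable) and two shape
#' parameters `sigma` and `mu`.  The hazard of the MWED is increasing
#' when `sigma >= 1` and bathtub-shaped when `sigma < 1`.
#'
#' All three parameters must be strictly positive and finite: at
#' `sigma = 0` or `mu = 0` the density degenerates, so the boundary is
#' excluded.
#'
#' @param theta positive scale parameter.
#' @param sigma positive shape parameter (controls the hazard shape).
#' @param mu positive shape parameter.
#' @return An object of class `mwed_params`: a named numeric vector with
#'   elements `theta`, `sigma`, `mu`.
#' @examples
#' p <- mwed_params(1, 2, 0.5)
#' unclass(p)
#' @export
mwed_params <- function(theta, sigma, mu) {
  p <- c(theta = as.numeric(theta), sigma = as.numeric(sigma), mu = as.numeric(mu))
  if (length(p) != 3L || anyNA(p) || any(!is.finite(p)) || any(p <= 0)) {
    stop("MWED parameters theta, sigma, mu must be single, finite, strictly positive numbers",
         call. = FALSE)
  }
  structure(p, class = "mwed_params")
}

#' @export
print.mwed_params <- function(x, ...) {
  cat(sprintf("MWED parameters: theta = %g, sigma = %g, mu = %g\n",
              x[["theta"]], x[["sigma"]], x[["mu"]]))
  invisible(x)
}

#' Coerce to an `mwed_params` object
#'
#' @param x an `mwed_params` object or a numeric vector of length 3
#'   ordered as (theta, sigma, mu).
#' @return An `mwed_params` object.
#' @export
as_mwed_params <- function(x) {
  if (inherits(x, "mwed_params")) return(x)
  if (is.numeric(x) && length(x) == 3L) {
    return(mwed_params(x[[1L]], x[[2L]], x[[3L]]))
  }
  stop("cannot coerce to mwed_params: supply a numeric vector (theta, sigma, mu)",
       call. = FALSE)
}
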