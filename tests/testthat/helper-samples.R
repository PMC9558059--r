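# Shared fixtures, built in code.

# a moderate, well-identified type-II sample used across tests
ts_sample <- function(n = 100, r = 80, truth = c(1, 1, 1), seed = 11) {
  generate_censored_sample(n, r, as_mwed_params(truth), seed = seed)
}

# parameter grid spanning the simulation study's truth values
param_grid <- list(
  c(1, 1, 1), c(1, 2, 1), c(1, 2, 2), c(2, 1, 1), c(2, 2, 2), c(2, 2, 1),
  c(0.1, 0.5, 0.1), c(0.1, 0.5, 0.5), c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.1),
  c(0.5, 0.1, 0.1), c(0.1, 0.1, 0.1)
)

# first interior (non-boundary) fit drawn from a seed sequence
interior_fit <- function(n = 100, r = 80, truth = c(1, 1, 1), seed0 = 11) {
  for (s in seed0 + 0:49) {
    smp <- generate_censored_sample(n, r, as_mwed_params(truth), seed = s)
    fit <- tryCatch(fit_mwed_mle(smp), error = function(e) NULL)
    if (!is.null(fit) && !fit$boundary) return(list(sample = smp, fit = fit))
  }
  stop("no interior fit found in 50 seeds")
}
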