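Package: mwedbayes
Title: Bayesian and Maximum-Likelihood Inference for the Modified
    Weibull Extension Distribution under Right Censoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distribution functions, random generation and censored-data
    likelihoods for the three-parameter Modified Weibull Extension
    distribution (MWED), a bathtub-hazard lifetime model for survival
    data.  Provides maximum-likelihood fitting under type-II and general
    right censoring, Bayes estimators under squared-error, precautionary,
    quadratic and entropy loss functions with gamma priors, a
    three-parameter Lindley approximation for posterior expectations with
    a deterministic quadrature oracle, a Monte-Carlo protocol for
    comparing the estimators by mean squared error, and two embedded
    censored cancer survival datasets with Kaplan-Meier overlays and
    goodness-of-fit summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
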