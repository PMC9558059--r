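# mwedbayes

Parametric survival analysis for right-censored lifetime data with the
three-parameter **Modified Weibull Extension distribution (MWED)** — a
bathtub-hazard model with scale θ and shapes σ, μ whose hazard rate

    r(x) = σ μ (x/θ)^(σ−1) exp[(x/θ)^σ]

is increasing for σ ≥ 1 and bathtub-shaped for σ < 1, with reliability
R(x) = exp[μθ(1 − e^{(x/θ)^σ})].  The package is aimed at
biostatisticians modeling censored medical follow-up (remission and
survival times) and at anyone studying small-sample behaviour of Bayes
estimators for weakly identified lifetime models.

It provides:

* distribution functions in the base-R `d/p/q/r` idiom (`dmwed`,
  `pmwed`, `qmwed`, `rmwed`, plus reliability `smwed` and hazard
  `hmwed`), with an inverse-transform sampler;
* censored likelihoods (type-II life tests and general right
  censoring), analytic gradients, and maximum-likelihood fitting on a
  compactified parameter space that makes the estimator well-defined
  even when the likelihood runs toward the model's Weibull limit
  (`fit_mwed_mle`);
* Bayes estimators under squared-error (SELF), precautionary (PLF),
  quadratic (QLF) and entropy (ELF) loss with independent gamma priors
  and prior-mean elicitation, computed either by a three-parameter
  Lindley expansion around the MLE (`lindley_expectation`,
  `bayes_estimates`) or by deterministic 3-D Gauss–Legendre quadrature
  of the exact posterior integrals (`posterior_moments_quadrature`),
  with posterior risks for every loss;
* the Monte-Carlo protocol comparing all five estimators by mean
  squared error under 20% type-II censoring (`run_study`), with full
  per-reason drop accounting;
* two embedded censored cancer datasets — 30 leukemia remission times
  (weeks, 5 censored) and 22 bile-duct-cancer survival times (days, 3
  censored) — with Kaplan–Meier curves and per-method goodness-of-fit
  summaries (`mwed_dataset`, `fit_dataset`, `km_estimator`);
* a small command line (`simulate`, `fit`, `oracle`) under
  `inst/cli/mwed.R`.

## Worked example

Fit the bile-duct-cancer dataset by maximum likelihood and all four
Bayes rules (empirical-Bayes gamma priors centred at the MLEs):

```r
library(mwedbayes)
fit <- fit_dataset(mwed_dataset("D2"), prior = "gamma")
fit
```

```
Dataset D2: survival times of 22 bile duct cancer patients (days); 22 observations, 3 censored
Fitted MWED parameters by method:
        theta   sigma      mu
MLE  7770.000 1.63641 0.02422
SELF 7699.802 1.62028 0.03119
PLF  7699.983 1.64274 0.04558
QLF  7699.071 1.52538 0.00788
ELF  7699.438 1.57365 0.01543
Empirical-fit MSE vs Kaplan-Meier cdf:
      MLE      SELF       PLF       QLF       ELF 
0.0043827 0.0050162 0.0200920 0.0562340 0.0135370 
```

The θ column sits at the cap of the compactified parameter space
(10 × the largest observation): for these data the MWED is
indistinguishable from its limiting Weibull, the likelihood increases
monotonically in θ, and the interior MLE does not exist — the fit is
flagged (`fit$mle$boundary`) and the Bayes moments are computed by exact
quadrature rather than the Lindley expansion, which needs a
well-conditioned information matrix.  The last line is the mean squared
vertical distance between each fitted cdf and the Kaplan–Meier empirical
cdf at the uncensored failure times: here maximum likelihood and the
squared-error-loss Bayes fit track the empirical curve most closely.

A desk-scale run of the simulation protocol (truth θ = σ = μ = 1,
n = 20 items, 20% censored, MLE only):

```r
res <- run_study(study_config(c(1, 1, 1), n = 20, replicates = 200,
                              seed = 7, methods = "mle",
                              max_drop_fraction = 0.5))
res
attr(res, "drop_reason")
```

```
   n parameter method      mean       mse
1 20     theta    MLE 0.8855236 0.8819165
2 20     sigma    MLE 0.9950218 0.1553674
3 20        mu    MLE 1.3295855 3.1475491
    nonconvergence           boundary information_not_pd incoherent_moments 
                 3                 48                  0                  0 
```

About a quarter of the n = 20 replicates end at the Weibull boundary,
where the MLE does not exist; they are dropped and counted, and the
reported means and MSEs are kept-replicate statistics.  The methods
vignette (`vignettes/mwed-censored-bayes.Rmd`) explains why this
weak identification is intrinsic to the model at small n and how it
shapes every downstream summary.

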