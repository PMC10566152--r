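# berksonjem

Berkson error adjustment for job-exposure-matrix (JEM) based
exposure-response estimation under a gamma exposure model.

## The problem

Occupational epidemiological studies typically cannot measure each subject's
exposure. A JEM assigns every occupation code a statistical summary of
measured full-shift exposure — arithmetic mean `AM` and standard deviation
`SD`, geometric mean `GM` and geometric standard deviation `GSD` (here
extremely-low-frequency magnetic fields, in µT) — and a subject's cumulative
exposure over job spells of durations `t_ij` (years) is

    CumMF_i = Σ_j t_ij · x_ij   (µT·years).

Plugging a fixed per-occupation level `x_ij` (AM, GM, or the "modified
geometric mean" MGM = GM·exp((ln GSD)²/2)) into a regression ignores that the
true individual exposure varies around the assigned value — Berkson
measurement error, which biases nonlinear models. Modelling the
within-occupation exposure as gamma with shape `AM²/SD²` and rate `AM/SD²`,
this package instead maximises the *marginal* likelihood obtained by
integrating the outcome model over the exposure distribution. For logistic
regression the marginal case probability is the alternating series

    p_i = Σ_{n≥0} (−1)^n e^{−nβ0} Π_j (1 + n β1 t_ij SD_j²/AM_j)^(−AM_j²/SD_j²)

(valid for β0 ≥ 0, β1 > 0, truncated at a configurable degree with a
reported tail bound); Poisson regression has an analogous series under the
validity constraint `β1·t_ij < AM_j/SD_j²`, and conditional logistic
regression for matched strata replaces each subject's SoftMax weight
`exp(β1·CumMF)` by the exact marginal Poisson mean
`Π_j (1 − β1 t_ij SD_j²/AM_j)^(−r_j)`. Adaptive-quadrature oracles for the
defining integrals, surrogate comparators, a synthetic cohort generator, and
a two-level Monte Carlo study engine (bias / SE / RMSE per estimator) round
out the package. See the vignette `vignettes/berkson-adjustment.Rmd` for the
model, assumptions, and numerical choices.

## Worked example

Simulate a 300-subject cohort from the gamma exposure world (true intercept
1, true slope 0.2 per µT·year) and estimate the slope four ways:

```r
library(berksonjem)

cohort   <- generate_cohort(cohort_config(n_subjects = 300), seed = 2024)
exposed  <- sample_exposures(cohort$histories, cohort$jem, seed = 2025)
cummf    <- cumulative_exposure(exposed)
outcomes <- simulate_outcomes_nonstratified(cummf, beta0 = 1, beta1 = 0.2, seed = 2026)

fit <- fit_exposure_response(cohort$jem, cohort$histories, outcomes,
                             model = "logistic", method = "adjusted")
fit
#> Berkson exposure-response fit
#>   model:  logistic
#>   method: adjusted
#> # A tibble: 2 × 3
#>   term  estimate std.error
#>   <chr>    <dbl>     <dbl>
#> 1 beta0   1.44       0.313
#> 2 beta1   0.0933     0.118
#>   logLik -131.572
```

`tidy()` and `glance()` return the estimates and the one-row fit summary as
tibbles. On this single draw all four methods land near 0.09-0.10 with
standard errors around 0.12 — one dataset of this size cannot separate the
estimators (the true slope 0.2 is within one SE of every estimate); the
study engine exists precisely to compare them over many replicates:

```r
study <- run_study(study_config_reduced(seed = 1))  # 200 subjects, 20 x 20 replicates
study$results   # bias, SE, RMSE per (true slope, method)
autoplot(study, "bias")
```

A command-line wrapper with `simulate`, `fit`, `run-study`, and
`kernel-eval` subcommands is installed at `inst/cli/bjem` (see `?bjem_cli`).

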