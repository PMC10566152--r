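---
title: "Berkson error adjustment for JEM-based exposure-response estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Berkson error adjustment for JEM-based exposure-response estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(berksonjem)
library(dplyr)
```

## The problem

Occupational case-control studies rarely observe individual exposures.
Instead, a job-exposure matrix (JEM) summarises measured full-shift exposure
for each occupation code — here extremely-low-frequency magnetic fields, in
microtesla (µT) — as an arithmetic mean `AM` and standard deviation `SD`,
together with a geometric mean `GM` and geometric standard deviation `GSD`.
A subject with job spells $j = 1, \dots, J_i$ of durations $t_{ij}$ years is
then assigned a cumulative exposure
$$\mathrm{CumMF}_i = \sum_{j=1}^{J_i} t_{ij}\, x_{ij} \quad (\mu\text{T-years}),$$
where $x_{ij}$ is some deterministic per-occupation level. Using a group
summary in place of the unknown individual exposure is *Berkson* measurement
error: the truth varies around the assigned value. Berkson error leaves
linear models unbiased but biases nonlinear ones — logistic, Poisson, and
conditional logistic regression included.

This package treats the within-occupation exposure as gamma distributed,
$$X_{ij} \sim \mathrm{Gamma}\!\left(r_j = \tfrac{AM_j^2}{SD_j^2},\;
\lambda_j = \tfrac{AM_j}{SD_j^2}\right),$$
which moment-matches the JEM summaries, and compares two estimation
strategies for the exposure-response slope $\beta_1$ (the log odds ratio per
µT-year):

* **Surrogate plug-in**: use a fixed level per occupation — `AM`, `GM`, or
  the "modified geometric mean" `MGM` — in an ordinary regression.
* **Berkson adjustment**: maximise the *marginal* likelihood obtained by
  integrating the outcome model over each spell's gamma distribution.

### The adjusted likelihoods

All marginal integrals reduce to evaluations of the gamma moment generating
function $M_X(t) = (1 - t/\lambda)^{-r}$, $t < \lambda$. Expanding the
logistic response in powers of $e^{-(\beta_0 + \beta_1 \sum t x)}$ gives the
alternating series implemented by `adjusted_logistic_prob()`:
$$p_i = \sum_{n \ge 0} (-1)^n e^{-n\beta_0}
\prod_j \left(1 + \tfrac{n \beta_1 t_{ij} SD_j^2}{AM_j}\right)^{-r_j},
\qquad \beta_0 \ge 0,\ \beta_1 > 0 .$$
The Poisson marginal pmf (`adjusted_poisson_logpmf()`) has an analogous
series with an extra $1/n!$ and a *validity constraint*: term $n$ exists only
while $(n + y)\,\beta_1 t_{ij} < \lambda_j$ for every spell. The marginal
mean of a log-linear Poisson response is exact (no series):
$$E[Y_i \mid \beta_1] = \prod_j \left(1 - \tfrac{\beta_1 t_{ij} SD_j^2}{AM_j}\right)^{-r_j},
\qquad \beta_1 t_{ij} < \lambda_j,$$
and conditioning independent such responses on one case per matched stratum
yields the adjusted conditional logistic likelihood
(`adjusted_conditional_loglik()`), a SoftMax over these marginal means.
A generic `mgf` argument accepts any user-supplied per-occupation MGF, so
non-gamma exposure models can be plugged into the same machinery; a
log-normal model has no MGF and is reachable only through a numerical
stand-in or the quadrature oracle.

### Truncation, and what the tail bound tells you

The series is truncated at `degree` $M$ (terms $n = 0..M$; default 10, which
is also what the fitting routines use). Because consecutive terms strictly
decrease in magnitude, the absolute truncation error is bounded by the first
omitted term, which `tail_check = TRUE` reports per subject. That bound is
**not uniformly small**: series decay is driven by $e^{-n\beta_0}$ and by the
MGF factors, so for $\beta_0$ near zero *and* small $\beta_1 t_{ij}
SD_j^2/AM_j$ the truncated value can be off by far more than quadrature
tolerance — e.g. the single-spell case $\beta_0 = 1,\ \beta_1 = 0.2,\ t =
10,\ AM = SD = 0.15$ already carries a truncation error of about $3 \times
10^{-6}$ at $M = 10$. When you need certified accuracy, either raise
`degree` until the reported tail bound is acceptable or use
`quadrature_oracle()`, which evaluates the defining integral by nested
adaptive quadrature and is also the only evaluation defined for negative
$\beta_0$ or $\beta_1$ (the series diverges there and is refused with a
classed error). In the fitted models the truncation error is dwarfed by
statistical noise whenever $\hat\beta_0$ is not close to zero.

The Poisson series is harsher: its terms grow like $e^{(n+y)\beta_0}/n!$
before decaying, and the validity constraint can cap the usable degree below
the requested one (a warning is emitted, and the returned `tail_ok` flag
records whether the retained terms had entered their decaying regime). For
subjects with large counts and long, high-variance spells the capped series
is genuinely unreliable; the fitting routine therefore bounds the intercept
search by the data ($e^{\beta_0}$ cannot exceed the mean response) and falls
back to a simplex search when the piecewise objective aborts the quasi-Newton
line search. Fits in that regime are flagged `converged = FALSE` rather than
silently trusted.

## Fitting

`fit_exposure_response()` covers the six (model, method) combinations.
Surrogate ordinary logistic and Poisson fits are delegated to `stats::glm()`
— they are standard GLMs once the surrogate CumMF is computed. The
conditional-logistic surrogate and all adjusted fits maximise the likelihoods
above directly: box-constrained quasi-Newton for the two-parameter models
(with an analytic gradient for the adjusted logistic series), golden-section
search for the one-parameter conditional models. Three numerical choices
matter:

* the adjusted Poisson / conditional searches are confined to
  $\beta_1 < \min_{i,j} AM_j / (SD_j^2\, t_{ij})$, shrunk by a relative
  margin of $10^{-6}$, because the likelihood blows up at the validity
  boundary;
* the surrogate-AM fit seeds the adjusted fit — the small-error limits make
  it the natural neighbourhood;
* $\beta_0 \ge 0$ is enforced for adjusted logistic/Poisson fits (a series
  hypothesis, and a documented limitation: data whose true intercept is
  negative push the estimate to the boundary).

Standard errors come from the numerical observed information; per-stratum
SoftMax terms are computed with max-subtraction and all likelihood products
accumulate in log space, with probabilities clipped to
$[10^{-12}, 1 - 10^{-12}]$.

## The synthetic cohort

The real data motivating this design are confidential, so
`generate_cohort()` builds a synthetic stand-in: a JEM of `n_jobs`
occupations, 1-5 job spells per subject with uniform durations, and 813
subjects by default with gender (2) × age group (4) × centre (3) covariates
whose interaction defines up to 24 matched strata under the stratified
design. Defaults were fixed once, from two a-priori considerations:

* plausible full-shift magnetic-field summaries — `AM` uniform on
  [0.1, 0.4] µT with coefficient of variation `SD/AM` uniform on [0.4, 0.8];
* the validity constraint must hold over the whole study slope grid
  (0-0.4 per µT-year) with margin: with spell durations at most 6 years the
  worst-case bound is $1/(0.8^2 \times 0.4 \times 6) \approx 0.65$.

`GM` and `GSD` are derived from the gamma law itself
($GM = e^{\psi(r)}/\lambda$, $GSD = e^{\sqrt{\psi'(r)}}$), keeping the JEM
internally consistent with the distribution the exposures are drawn from.
The paper-trail definition of `MGM` is nowhere algebraic, so the package
adopts the log-normal mean $GM \cdot e^{(\ln GSD)^2/2}$ — the mean of the
log-normal with median `GM` and geometric SD `GSD` — and documents that as a
design choice.

Outcome simulation follows the two printed designs. Non-stratified: case
status is Bernoulli with the standard logistic probability
$1/(1 + e^{-\beta_0 - \beta_1 \mathrm{CumMF}_i})$ — the source text prints
$1/(1 - e^{-\cdots})$, which exceeds one for positive arguments; we read the
sign as a typo, consistent with the likelihood the method maximises.
Stratified: one case per stratum, drawn from a single-trial multinomial with
SoftMax probabilities computed from *each subject's own* cumulative exposure
(the printed subscripts mix the case's exposures into other subjects' terms;
we read the intent as own-history throughout). Both readings are
interpretation choices and are worth knowing when comparing against other
implementations.

What the generator does **not** emulate: any correlation between covariates
(hence strata) and job histories, occupational clustering, secular trends in
exposure, or non-gamma within-occupation variation. Passing tests therefore
certify the estimators under the gamma exposure world with
stratum-independent histories — not performance on any real cohort. This
matters for the stratified design especially: with own-history SoftMax
assignment and histories independent of strata, conditional logistic
estimation is correctly specified up to Berkson noise, and Berkson noise
induces only second-order bias there — under these conditions the adjusted
and AM conditional estimators are close to unbiased, and claims of stratified
non-identifiability found elsewhere do not reproduce.

## The simulation study

`run_study()` nests two Monte Carlo levels per true slope: the outer level
re-draws per-spell exposures (JEM and histories fixed), the inner level
re-draws outcomes and re-estimates $\beta_1$ by every method. Per outer
replicate the *median* of inner estimates is kept (the estimate distribution
is right-skewed); across outer replicates the mean and the 2.5%/97.5%
percentiles of those medians are reported. The variance entering SE and RMSE
is the total variance — mean of within-outer population variances of the raw
estimates plus the population variance of the outer means — so
$\mathrm{RMSE}^2 = \mathrm{bias}^2 + \text{total variance}$ holds exactly,
and the decomposition equals the pooled population variance of all raw
estimates. Population (not $n-1$) variances are used throughout to keep the
decomposition exact. Percentiles are taken over outer-replicate medians; an
alternative reading (percentiles of all raw estimates) exists, but medians
are what the aggregation pipeline propagates.

Failed or non-converged fits are excluded and counted per cell, never
imputed; fully failed cells surface as `NA` rows and plot as gaps.
Reproducibility is by construction: a master seed spawns one substream per
(slope, outer replicate) cell, so serial and forked-parallel execution give
byte-identical tables.

The default configuration is the full design (813 subjects, slope grid 0 to
0.4 in steps of 0.01, 100 × 100 replicates) and takes hours;
`study_config_reduced()` — 200 subjects, slopes {0.1, 0.2, 0.3}, 20 × 20 —
is the desk-scale preset the test suite and the acceptance script use, and
runs in minutes. At that reduced scale the per-method bias differences are
comparable to Monte-Carlo error (MCSE ≈ 0.008 on the $\beta_1$ scale), so
ordering statements among estimators are made *within* Monte-Carlo error;
resolving the strict ordering requires the full-scale preset.

```{r example, eval = FALSE}
study <- run_study(study_config_reduced(seed = 1))
study$results
autoplot(study, "bias")
```

## Known limitations

* The adjusted logistic series with the default degree is inaccurate near
  $\beta_0 = 0$ with weak exposure decay; raise `degree` or consult the tail
  bound (see above).
* Adjusted Poisson fitting outside the series' convergent regime (large
  counts, long high-variance spells, intercepts much above zero) is flagged,
  not solved; the validity cap is a hard analytic limit of the gamma model.
* $\beta_0 \ge 0$ is required by the adjusted logistic/Poisson fits.
* Conditional models fit $\beta_1$ only; no covariate adjustment beyond
  stratification is offered.
* `quadrature_oracle()` supports at most three spells per history (nested
  adaptive quadrature); it is a verification tool, not a fitting backend.
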