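---
title: "Models and methods behind eldercast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind eldercast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eldercast)
```

`eldercast` estimates a five-state discrete-time health transition model
from two-wave elderly panel data, fits a two-part model of medical
expenditure, projects the population by health state with
Chapman–Kolmogorov matrix powers, and aggregates head counts with
per-capita costs into expenditure forecasts. This vignette records the
models, their assumptions, the numerical choices, and what the synthetic
generator does and does not emulate.

## The state space

Self-rated health is collapsed to four living states — 1 healthy,
2 basically healthy, 3 unhealthy, 4 very unhealthy — plus death (state 5).
States 1–4 are transient; death is absorbing, so row 5 of every
transition matrix is exactly (0, 0, 0, 0, 1) and this is enforced by the
`transition_matrix()` constructor rather than merely checked in tests.
The estimation period is two years, the spacing of the survey waves; all
matrices carry a `period_years` attribute.

## Transition estimation

The data are matched person-level pairs (origin state at wave 1,
destination state at wave 2, wave-1 covariates). Two parameterizations
are exposed:

* **Multinomial (canonical).** A multinomial logit over destinations with
  destination 1 as reference, origin entering as four indicators and
  covariates linearly. Predicted rows are stochastic by construction,
  which the projection stage requires. Fitting uses `nnet::multinom`
  with a tight convergence tolerance (`reltol = 1e-13`) so that the
  intercept-only fit reproduces the empirical frequency matrix to
  better than 1e-6 — the saturated-model identity that serves as the
  analytic oracle in the tests.
* **`binary_renormalized` (compatibility).** One binary logit per
  destination, mirroring a per-destination odds formulation. Separate
  binary logits do not guarantee unit row sums, so predicted rows are
  renormalized. On large synthetic panels the two modes agree entrywise
  to well under 0.02; both are kept because the literal per-destination
  odds model remains in use even though it is not self-consistent.

Sample-average prediction (`predict_transition_matrix(fit)`) averages
predicted probability rows over the fitting sample's covariate rows —
a population-averaged matrix — rather than predicting at the covariate
means, which matches the population-level reading of published transition
tables. Origin states unobserved at fitting yield `NA` rows with a
warning, never silent zeros. Age-stratified matrices
(`stratified_matrices()`) use the empirical estimator per five-year band;
bands with too few pairs or missing origins are flagged and excluded.

No interactions between origin and covariates are fitted by default, no
covariates-of-death submodel is included, and continuous-time
(hazard-rate) multistate modelling is out of scope: the model is strictly
a two-year discrete-step chain.

## Two-part expenditure model

Zero expenditure is common and informative, so the outcome is modelled in
two parts: a probit for any-expenditure, and a linear level-scale (yuan)
equation estimated by least squares on the positive observations. Because
the joint likelihood factorizes, the separately estimated probit MLE and
OLS fit are jointly the maximum-likelihood estimate; the combined
log-likelihood is reported with the residual scale at its MLE
$\hat\sigma = \sqrt{\mathrm{SSR}/n_+}$. The level part is deliberately
untransformed (no log, no smearing retransformation): the published
per-capita values the pipeline consumes are level-scale. The
unconditional mean is $\Phi(x'\delta_1)\max(x'\delta_2, 0)$; the floor at
zero handles covariate profiles whose linear prediction would otherwise
be negative, since expenditure cannot be. Per-state tables average this
fitted mean over the covariate rows of the panel members in each cell;
empty cells are `NA` and flagged, never zero. Monthly individual values
annualize by an exact factor of 12 (`annualize_monthly()`), and the
"times higher" contrast is `value(state 4)/value(state 1) − 1`, reported
at two decimals.

## Projection

`n_step_matrix()` computes matrix powers by exponentiation-by-squaring
with a row-renormalization guard, preserving row-stochasticity to 1e-10
over the horizons used. `project_cohorts()` advances each age band's
state vector one two-year step at a time, accumulating deaths in the
fifth component so that living + cumulative deaths − cumulative entrants
equals the base total to 1e-6 persons in every year (a tested invariant).

Three modelling choices were genuinely open and are resolved as follows:

* **Annualization.** Kernels are biennial but forecasts are wanted
  annually. Annual values are obtained by linear interpolation between
  the two-year grid points — transparent, invertible, and free of the
  negativity/renormalization issues a matrix square root can introduce.
  (A principal-root mode was considered and rejected as the default for
  exactly that reason.)
* **Aging across five-year bands.** Under a uniform-within-band age
  distribution, a two-year step moves 2/5 of each band's post-transition
  living population into the next band; the open-ended oldest band
  retains everyone. This is the standard demographic approximation; it
  is an approximation, and cohort-by-single-year-of-age bookkeeping is
  the known alternative it trades away for simplicity.
* **Entrants.** People turning 60 are exogenous. The schedule is a
  required input (per-calendar-year counts summed over each step) with a
  default entry-state distribution equal to the baseline transient-state
  shares renormalized. The bundled `entrants_demo.csv` (a flat 20 million
  per year) is a demonstration convention, not a demographic estimate:
  projection levels driven by it are illustrative only.

Published matrices are printed at four decimals, so their rows can sum to
1 ± 3e-4; the loader tolerates deviations up to 5e-4 and rescales rows to
sum exactly to 1 before any power is taken, because Chapman–Kolmogorov
composition amplifies row-sum drift geometrically. One bundled
age-specific matrix (65–69) has a first row that sums to 1.0100 as
printed — an apparent typographical defect in the source table, far
beyond rounding; the fixture loader admits it under a widened tolerance
and renormalizes, and this is the only fixture treated that way.

## Actuarial aggregation

Totals are head count × per-capita value, linear and homogeneous in the
population (property-tested on random inputs). Two bases are exposed:
`published_monthly` multiplies annual head counts by monthly individual
per-capita values — verified by direct multiplication to be the
arithmetic behind the published 2035 totals — and `annual`
(= 12 × monthly, exactly) as the economically meaningful default for new
analyses. Discounting is not applied: totals are nominal yuan. The
published per-age endpoint totals are themselves bundled as anchors, and
change statistics between years are computed from them directly, because
the per-age population × per-capita products do not reproduce all printed
2035 endpoints (the 60–64 change is also internally inconsistent in the
source by 0.063 billion, and is excluded from the checks).

## The synthetic generator

The generator is the exact generative inverse of the two estimation
models: wave-2 states are drawn from the multinomial-logit kernel
(`truth_from_kernel()` inverts any strictly positive kernel into
intercept-only coefficients, exactly), and expenditures from the
probit × truncated-normal level process. Truncation at zero (rather than
resampling) preserves a closed-form mean for recovery tests; recovery
truths therefore keep the level predictor several residual SDs above
zero so truncation is negligible. Participation and zero expenditure are
linked exactly: `sought_care == 0` iff recorded expenditure is 0.

Default conditions mirror the study design the generator emulates:
5,487 individuals, baseline state shares (0.1215, 0.2982, 0.3849,
0.1954), ages 60–89, a two-year step, and a covariate battery
(demographics, socioeconomic status, health behaviours, social
relations) with conventional distributions — P(female) = 0.5,
BMI ~ N(23, 3), and so on. These distributions are generator
conventions, not estimates of any survey's composition. The generator
does not emulate sampling weights, household clustering, attrition, or
item nonresponse; passing recovery tests therefore demonstrates
correctness of the estimators under the stated models, not robustness to
those real-data complications.

## Numerical choices and test design

* Degenerate inputs: zero-origin-count rows are estimation errors naming
  the state; all-zero or all-positive outcomes make the two-part model
  unidentified and error; a perfect-fit level part (σ = 0) drops the
  degenerate normal terms from the reported likelihood.
* Problem sizes: recovery suites use n = 50,000 panels for kernel
  recovery (with a fixed five-seed χ² batch at α = 0.01, the calibrated
  formulation for twenty simultaneous cell checks), 200 replicates at
  n = 5,000 for two-part coefficient coverage against 99% Wald
  intervals, and 50 replicates at n = 2,000 for multinomial coefficient
  coverage. These sizes make the full suite run in well under a minute
  while leaving Monte-Carlo error far below the tested tolerances.
* Determinism: every stochastic function takes a seed; identical seeds
  give byte-identical artifacts, a tested contract of `run_pipeline()`.

## Known limitations

Transition estimates condition on wave-1 covariates only; time-varying
covariates are out of scope. The projection treats kernels as
age-group-specific but time-invariant. Entrant schedules and base
populations determine forecast levels entirely — with demo entrants the
levels are demonstrations. Family-level and individual-level totals
should not be summed (double counting). Gender-stratified kernels and
GDP-share statistics are not implemented for lack of validating inputs.
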