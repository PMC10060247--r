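---
title: "Methods: risk-stratified estimation of treatment effect heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk-stratified estimation of treatment effect heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`RiskStratEffects` estimates how the effect of a target treatment versus a
comparator varies with predicted baseline outcome risk in observational
time-to-event cohorts. The pipeline is: build analysis-ready populations
with prior-outcome exclusion; fit an outcome-risk model on a 1:1
propensity-matched subset; split subjects into risk groups; within each
group, re-fit a propensity model, stratify into score quintiles, estimate a
Cox hazard ratio and a Kaplan–Meier risk difference per stratum, and pool;
gate everything behind balance, overlap and negative-control diagnostics.

The central scientific point is scale dependence: with a constant relative
effect and a discriminating risk model, absolute risk differences must grow
with baseline risk, so results are always reported on both scales.

# Data model and population construction

A cohort table has one row per subject (`subject_id`, `arm`, `obs_end`,
covariate columns); an outcome table has rows (`subject_id`, `outcome_id`,
`event_time`) with times in integer days relative to treatment initiation —
non-positive times are medical history. For each outcome,
`buildStudyPopulation()`:

* excludes subjects with any record at `event_time <= 0` from that
  outcome's analysis set (day 0 counts as prior — the conservative reading
  of "any time prior to treatment initiation"). A config switch
  (`priorExclusionWindow = "lookback"`) restricts exclusion to the lookback
  window instead of all-time history; all-time is the default because
  history-based exclusion criteria rarely expire.
* assigns `tte = min(first post-index event, obs_end, horizon)` and
  `event = 1` iff the first post-index event falls at or before both
  truncations. Only the earliest event per subject and outcome is used.
* uses an intention-to-treat time-at-risk: follow-up is truncated at the
  fixed horizon (default 730 days) and never at treatment discontinuation,
  which keeps the estimand simple and avoids informative censoring by
  adherence.

Covariates are assumed pre-computed at index. Subjects with `obs_end = 0`
carry no follow-up and are dropped from analysis sets.

# Prediction step

The outcome-risk model is an L1-penalized logistic regression of "event
within horizon" on all covariates, fitted by default on the 1:1
propensity-matched subset so the model cannot fit the two arms
differentially (which would manufacture spurious treatment interactions).
Details and defaults:

* λ grid: `glmnet` with 50 log-spaced values down to `1e-4` of λ_max;
  selection by minimum 3-fold cross-validated deviance, no 1-SE rule (the
  plain minimum is the simplest defensible choice; consequently a few
  noise covariates may survive selection — sparsity at the CV minimum is
  draw-dependent).
* folds are seeded and stratified by outcome so no fold is single-class.
* covariates are standardized inside the fit; coefficients are reported on
  the original scale; prediction treats absent covariates as 0 (sparse
  absence semantics).
* discrimination: the c-statistic with a DeLong-type asymptotic 95% CI,
  reported in four populations (matched = development set, treatment,
  comparator, entire); for the matched set both the apparent and the
  cross-validated estimate (from prevalidated out-of-fold predictions) are
  given, since the apparent value on the development data is optimistic.

Risk groups are half-open intervals `[t_i, t_{i+1})` of predicted risk: a
risk exactly at a threshold goes to the *higher* group (the natural reading
of "below 1%" / "between 1% and 1.5%"). Both absolute thresholds and
quantile groups are supported; simulated studies in this package default to
predicted-risk tertiles because absolute cutoffs like 1%/1.5% only make
sense for a particular real risk distribution.

# Propensity machinery

* The propensity model uses the same LASSO machinery as prediction, per
  scope (globally for matching; re-fitted within each risk group for
  estimation, since covariate–treatment associations can differ across risk
  strata).
* Matching is greedy 1:1 nearest-neighbour without replacement; target
  subjects are processed in a seeded random order; the caliper is 0.2
  times the SD of the logit of the score (`caliperScale = "std_logit"`,
  the prevailing convention; `"raw"` available). Greedy rather than optimal
  matching keeps the step deterministic and fast; matched-set ATT
  estimation is supported implicitly via `subsetPopulation()` but the
  default estimand is ATE-within-risk-group via stratification.
* Stratification uses k-quantiles (default k = 5) of the score over the
  pooled population (pooled is symmetric in the arms; a target-only
  variant would target ATT). Boundary scores go to the lower stratum; tied
  quantiles collapse with a `degenerate_ps` diagnostic.
* The preference score F solves `logit F = logit S − logit φ` (φ = target
  prevalence); F = 0.5 is clinical equipoise. Overlap between arms is the
  overlapping coefficient of the two preference-score histograms on 100
  fixed equal-width bins — a deterministic choice that avoids kernel
  bandwidth selection; the exact metric behind published overlap
  percentages is not standardized, so this definition is documented rather
  than assumed universal.

# Estimation and pooling

Per stratum and outcome:

* Cox: single-covariate (treatment indicator) partial likelihood with
  Breslow tie handling, Newton iterations to gradient tolerance 1e-9.
  Strata with no events or a single arm are flagged inestimable; monotone
  likelihoods (|log HR| > 20 or se > 50) likewise, with the reason kept in
  the audit table.
* Kaplan–Meier: survival at the horizon per arm with Greenwood variance;
  `rd = S_target(h) − S_comparator(h)` (= comparator minus target
  cumulative incidence), so positive values favour the target arm. If the
  horizon exceeds the last observed time, survival is carried forward and
  the component flagged `extrapolated`.

Pooling: log hazard ratios are combined by inverse-variance weighting
("averaging over the hazard-ratio estimates" is not fully specified;
IVW is the standard estimable choice and degrades gracefully when strata
are sparse — an equal-weight `arithmetic_log` option is provided). Risk
differences are combined with stratum-size weights, approximating the
average treatment effect over the risk group; the pooled se is
`sqrt(Σ (w_i/Σw)² se_i²)` and CIs are Wald on the estimation scale
(bootstrap deliberately omitted for determinism).

The overall row repeats the identical procedure on the ungrouped
population — one propensity model, five quintiles, pooled — so overall and
risk-group estimates are methodologically comparable.

# Diagnostics and suppression

* Balance: SMD per covariate before adjustment, and after as the
  stratum-size weighted combination of within-stratum means and variances.
  The gate fails when any post-adjustment |SMD| exceeds the threshold
  (default 0.1 — the conventional rule of thumb, configurable).
* Overlap: preference-score overlap below a floor (default 20%) marks a
  scope as lacking equipoise.
* A failed gate does not delete results: cells are flagged
  `suppressed` with a machine-readable reason and retained for audit,
  mirroring how published analyses withhold rather than discard
  non-reportable strata.
* Negative controls: outcomes with true HR = 1 are analysed by the same
  pipeline; their estimates y_i with sampling errors se_i are modelled as
  y_i ~ N(μ + b_i, se_i²), b_i ~ N(0, σ²), giving the closed-form marginal
  likelihood N(y_i; μ, σ² + se_i²) maximized by L-BFGS-B with σ ≥ 0.
  Calibrated intervals are `(logHR − μ) ± 1.96 √(se² + σ²)`; the calibrated
  p-value evaluates the estimate against N(μ, σ² + se²). Calibration
  models are fitted per risk group and for the overall scope (whether
  published analyses share one model per database is unclear; both are
  available).

# The simulator

`simulationScenario()` emulates the structure of a claims-database
comparative cohort: independent Bernoulli and standard-normal covariates;
logistic treatment assignment on those covariates (optionally plus an
unmeasured standard-normal confounder); exponential event times with log
rate `logRate + β·x + z·γ(x)` where `γ(x) = γ0 + γ1·(β·x)` allows constant
or risk-dependent log hazard ratios; exponential censoring truncated
administratively; negative-control outcomes with treatment coefficient
exactly 0 (and optionally an unmeasured-confounder loading to inject
residual bias). Exponential event times were chosen so marginal quantities
have closed forms for testing; the interface leaves room for a Weibull
extension. Seeding uses named substreams (covariates, assignment,
censoring, outcomes, controls) so that, e.g., changing the number of
negative controls leaves the cohort draw untouched.

What the simulator does *not* emulate: coded vocabularies and visit-level
records, correlated/time-varying covariates, competing risks, informative
censoring, and measurement error in outcomes. Passing validation on these
synthetic cohorts therefore demonstrates the statistical machinery under
its own assumptions, not robustness to real claims-data pathologies.

Built-in study conditions (chosen once as realistic for a first-line
treatment comparison):

* `scenarioNullControls()` — 10 confounders (assignment log-odds up to
  0.5), null primary outcome with mean 2-year risk 3%, negative controls
  with 2-year baseline risks log-uniform ≈1.4–4.3%.
* `scenarioStrongConfounding()` — 20 covariates with a tapered confounding
  profile (a few strong shifts up to 1.0 log-odds plus a weak tail, the
  usual shape of claims-data confounding; a profile in which *all* 20
  covariates are near-maximal confounders produces joint confounding that
  five quantile strata mathematically cannot remove and is not what
  stratified designs are meant for).
* `scenarioConstantEffect()` — constant conditional HR (default 0.8) with
  a strongly discriminating outcome model, mean 2-year risk 5%.

Baseline log rates are calibrated numerically (fixed-seed Monte Carlo +
root finding) to hit the stated mean risks rather than set as raw
intercepts.

`trueMarginalEffects()` is the ground-truth oracle: a large Monte-Carlo
draw (default 1e6) evaluates both potential outcomes per subject in closed
form, groups subjects by treatment-free mixture risk `(p0 + p1)/2`, and
reports per group the true event probabilities, risk difference, and the
marginal log HR defined as `log(log S̄1(h) / log S̄0(h))` — exact for
homogeneous strata under exponential times, and subject to the same mild
non-collapsibility attenuation a stratified Cox estimate sees.

# Validation design and problem sizes

The test suite validates each primitive against an independent oracle
(brute-force Breslow partial-likelihood maximization, hand product-limit /
Greenwood computation, all-pairs c-statistic placements, grid-search MLE
for the calibration model) and the pipeline end-to-end on simulated
studies: negative-control CI coverage at n = 20,000 with 200 controls
across two replicates (binomial Monte-Carlo tolerance ≈ ±3 percentage
points around 95%); pre- vs post-stratification balance at n = 20,000 with
20 covariates; and recovery of a constant conditional HR of 0.8 over 50
replicates of n = 20,000, checking per-risk-group CI coverage of the
oracle truth and the increasing pattern of absolute risk differences.
Because adjacent low-risk tertiles differ by fractions of a percentage
point in true risk, the monotonicity check permits an adjacent decrease of
at most its 95% Monte-Carlo margin (1.96·se of the pairwise difference) —
a strict sign test at this sample size would measure Kaplan–Meier noise,
not the scale-dependence property. These sizes keep the whole suite at a
few minutes on a single core while leaving Monte-Carlo error well inside
the asserted tolerances.

# Known limitations

* No competing-risk (sub-distribution hazard) estimation; events are
  censored at the horizon regardless of intervening death.
* No inverse-probability weighting estimator (stratification and matching
  only); weighting is a declared extension point.
* No cross-database meta-analytic pooling: multiple databases are
  independent runs combined only at the reporting layer.
* Wald intervals throughout; per-stratum Cox intervals can undercover when
  event counts per stratum are very small (such strata are flagged).
* The external-model import path (using a published risk model instead of
  an internally fitted one) is not implemented.
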