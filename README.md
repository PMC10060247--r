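# RiskStratEffects

Risk-stratified assessment of treatment effect heterogeneity in
observational comparative cohorts.

## The problem

Average treatment effects from comparative cohort studies rarely apply
uniformly: patients at different baseline outcome risk can experience very
different *absolute* benefit even when the *relative* effect (hazard ratio)
is constant. `RiskStratEffects` implements a standardized five-step
pipeline for examining this scale dependence in observational
time-to-event data, for epidemiologists and comparative-effectiveness
researchers working with person-level cohort tables (one row per subject:
treatment arm, observation end, baseline covariates; plus an event table
of outcome times relative to treatment initiation):

1. **Study definition** — target cohort *T* vs comparator cohort *C* with
   respect to outcomes *O₁…Oₙ*, a fixed time-at-risk horizon (default 2
   years, intention-to-treat), and per-outcome exclusion of subjects with
   the outcome at any time before treatment initiation.
2. **Data** — any number of databases, each analysed independently; a
   built-in simulator generates confounded cohorts with known ground
   truth so every stage can be validated without proprietary data.
3. **Prediction** — a LASSO logistic model for outcome risk within the
   horizon, fitted on the 1:1 propensity-matched subset (caliper 0.2 on
   the standardized logit scale) so the model is not fitted
   differentially between arms; λ chosen by 3-fold cross-validated
   deviance; discrimination (c-statistic, DeLong 95% CI) reported in the
   matched, treatment, comparator and entire populations. Predicted risk
   defines risk groups (absolute thresholds such as 1% / 1.5%, or
   quantiles).
4. **Estimation** — within each risk group, a fresh LASSO propensity
   model S = P(T | x); subjects are stratified into 5 propensity-score
   quintiles; per stratum a single-covariate Cox model (Breslow ties)
   gives log HR ± se and Kaplan–Meier curves give the risk difference at
   the horizon (Greenwood variance); strata are pooled by inverse
   variance on the log-HR scale and by stratum size for risk
   differences. Diagnostics gate every cell: standardized mean
   differences ≤ 0.1 after stratification, preference-score
   (logit F = logit S − logit φ) overlap above a floor, and
   negative-control outcomes (true HR = 1) fitted with a Gaussian
   systematic-error model N(μ, σ²) for empirical CI calibration.
5. **Presentation** — tidy tables of relative *and* absolute effects per
   risk group with suppression flags and machine-readable reasons.

## Worked example

A simulated study with a constant conditional hazard ratio of 0.8 and a
strongly risk-discriminating outcome model:

```r
library(RiskStratEffects)

scenario <- scenarioConstantEffect(n = 10000, hr = 0.8, seed = 42)
config   <- studyConfig(scenario = scenario, riskQuantiles = 3, seed = 42)
report   <- runStudy(config)
print(report)
#> Risk-stratified study report (seed 42 )
#> Pooled effect estimates ( 4 cells )
#>    scope outcome_id    hr hr_lo  hr_hi      rd    rd_lo   rd_hi suppressed
#>  overall  outcome_1 0.677 0.541  0.847 0.01640  0.00659 0.02613      FALSE
#>     RG-1  outcome_1 2.250 0.204 24.870 0.00255 -0.00249 0.00759      FALSE
#>     RG-2  outcome_1 0.438 0.209  0.918 0.01220  0.00225 0.02223      FALSE
#>     RG-3  outcome_1 0.704 0.553  0.897 0.03820  0.01138 0.06510      FALSE

print(report$risk_model)
#> Risk model for 'outcome_1' (730-day horizon): 8052 subjects, 260 events,
#>   8 nonzero coefficients at lambda = 0.00098566 (matched population)
#>   cross-validated c-statistic: 0.841 (0.818, 0.864)
```

Reading the grid: `hr` is the pooled hazard ratio of target vs comparator
(values < 1 favour the target treatment), `rd` the pooled risk difference
at 2 years (comparator minus target cumulative incidence, so positive
values favour the target). The absolute benefit rises from 0.3% in the
lowest-risk tertile to 3.8% in the highest — the scale-dependence pattern
the pipeline is designed to expose — while the wide RG-1 interval shows
how little relative-effect information low-risk patients carry (few
events). The ground-truth oracle for the same scenario,

```r
trueMarginalEffects(scenario, quantiles = 3, nMc = 5e5, seed = 42)
#>     scope p_target p_comparator       rd    hr
#>   overall  0.04139      0.05012 0.008730 0.822
#>      RG-1  0.00304      0.00379 0.000757 0.800
#>      RG-2  0.01441      0.01798 0.003565 0.800
#>      RG-3  0.10672      0.12859 0.021868 0.820
```

confirms the true risk differences 0.08% / 0.36% / 2.2% are increasing
while the true marginal hazard ratio stays ≈ 0.8 in every group.

`renderTables(report, "out/")` writes the effect grid, per-stratum audit
components, balance / overlap / negative-control diagnostic tables and
calibration parameters as headered CSV. A thin command-line wrapper lives
at `inst/cli/riskstrat.R` (subcommands `simulate` and `run`, YAML
configuration).

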