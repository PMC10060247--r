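Package: RiskStratEffects
Title: Risk-Stratified Assessment of Treatment Effect Heterogeneity in
    Observational Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A standardized five-step pipeline for risk-based assessment of
    treatment effect heterogeneity in observational comparative cohort data:
    construction of time-to-event study populations with prior-outcome
    exclusion, LASSO outcome-risk prediction on a propensity-matched subset,
    risk-group stratification, within-risk-group propensity score estimation
    and quintile stratification, pooling of Cox hazard ratios and
    Kaplan-Meier risk differences per risk group, and a diagnostic battery
    (covariate balance, preference-score equipoise overlap, and
    negative-control empirical calibration).  Includes a simulator for
    confounded survival cohorts with known ground truth so that every
    pipeline stage can be validated without access to proprietary claims
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    survival,
    stats,
    utils,
    jsonlite,
    yaml,
    data.table,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
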