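# Small in-code fixtures shared across test files.

# A 5-subject cohort with hand-enumerable follow-up truncation.
toyCohorts <- function() {
  data.frame(
    subject_id = paste0("s", 1:5),
    arm = c("target", "target", "comparator", "comparator", "target"),
    obs_end = c(730, 365, 50, 730, 730),
    prior_cvd = c(1, 0, 0, 1, 0),
    age_65 = c(0, 1, 0, 1, 1),
    stringsAsFactors = FALSE
  )
}

toySpec <- function(...) studySpec(outcomeIds = "O1", ...)

# Build a study population from a plain covariate matrix + binary labels:
# label-1 subjects get an event at day 100.
popFromLabels <- function(X, y, arm = NULL, obsEnd = 730) {
  n <- nrow(X)
  ids <- sprintf("p%05d", seq_len(n))
  if (is.null(arm)) arm <- rep(c("target", "comparator"), length.out = n)
  cohorts <- data.frame(subject_id = ids, arm = arm, obs_end = obsEnd,
                        stringsAsFactors = FALSE)
  cohorts <- cbind(cohorts, as.data.frame(X))
  outcomes <- if (any(y == 1)) {
    data.frame(subject_id = ids[y == 1], outcome_id = "O1",
               event_time = 100, stringsAsFactors = FALSE)
  } else {
    NULL
  }
  buildStudyPopulation(cohorts, outcomes, studySpec(outcomeIds = "O1"))
}

# Small fast scenario for end-to-end tests.
smallScenario <- function(n = 3000, nControls = 0, seed = 1) {
  simulationScenario(
    n = n,
    binaryPrevalence = c(0.2, 0.4),
    nContinuous = 2,
    treatCoefs = c(0.4, -0.3, 0.3, -0.2),
    outcomes = list(
      list(id = "outcome_1", logRate = log(6e-05),
           coefs = c(0.3, 0.2, 0.8, 0.3), gamma0 = 0, gamma1 = 0),
      list(id = "outcome_2", logRate = log(4e-05),
           coefs = c(0.2, 0.3, 0.5, 0.2), gamma0 = log(0.7), gamma1 = 0)
    ),
    nNegativeControls = nControls,
    ncLogRateRange = log(c(4e-05, 1e-04)),
    seed = seed
  )
}
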