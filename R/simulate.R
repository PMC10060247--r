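# Synthetic observational-study generator with known ground truth:
# confounded treatment assignment, exponential survival outcomes with
# (optionally risk-dependent) treatment effects, administrative censoring,
# and negative-control outcomes with true hazard ratio 1.

#' Describe a simulation scenario
#'
#' Covariates are independent Bernoulli (`binaryPrevalence`) and standard
#' normal (`nContinuous`) draws, named `x1..xp` (binary first).  Treatment is
#' assigned by a logistic model on the covariates (plus an optional
#' unmeasured standard-normal confounder).  Each outcome has exponential
#' event times with log rate `logRate + coefs . x + z * gamma(x)` per day,
#' where `z` is the target-treatment indicator and
#' `gamma(x) = gamma0 + gamma1 * (coefs . x)` allows both constant and
#' risk-dependent log hazard ratios.  Observation ends at
#' `min(Exp(censorRate), maxFollowup)` days.  Negative-control outcomes have
#' treatment coefficient exactly 0 by construction; their baseline log rates
#' are drawn log-uniformly on `ncLogRateRange` and their covariate
#' coefficients from `N(0, ncCoefSd)`; `ncBias` injects an unmeasured
#' confounder into control hazards to emulate residual confounding.
#'
#' @param n Number of subjects.
#' @param binaryPrevalence Prevalences of the binary covariates.
#' @param nContinuous Number of standard-normal covariates.
#' @param treatIntercept,treatCoefs Logistic treatment-assignment model.
#' @param outcomes List of outcome definitions; each a list with elements
#'   `id`, `logRate` (log events/day at covariates 0, arm comparator),
#'   `coefs` (length p), `gamma0`, `gamma1`.
#' @param censorRate Exponential censoring rate (1/days).
#' @param maxFollowup Administrative truncation of observation (days).
#' @param nNegativeControls Number of negative-control outcomes.
#' @param ncLogRateRange Range of control baseline log rates (log 1/days).
#' @param ncCoefSd SD of control covariate coefficients.
#' @param ncBias Coefficient of the unmeasured confounder in control hazards.
#' @param unmeasuredAssignmentCoef Coefficient of the unmeasured confounder
#'   in the assignment model (0 = fully measured confounding).
#' @param priorEventProb Probability that a subject carries a pre-index
#'   history record for each primary outcome.
#' @param seed Base seed; all draws use named substreams derived from it, so
#'   e.g. changing `nNegativeControls` does not perturb the cohort.
#' @return An object of class `simulationScenario`.
#' @export
simulationScenario <- function(n = 20000,
                               binaryPrevalence = c(0.1, 0.2, 0.3, 0.4, 0.5),
                               nContinuous = 5,
                               treatIntercept = 0,
                               treatCoefs = NULL,
                               outcomes = NULL,
                               censorRate = 1 / 1095,
                               maxFollowup = 1095,
                               nNegativeControls = 0,
                               ncLogRateRange = log(c(2e-05, 6e-05)),
                               ncCoefSd = 0.3,
                               ncBias = 0,
                               unmeasuredAssignmentCoef = 0,
                               priorEventProb = 0,
                               seed = 1) {
  p <- length(binaryPrevalence) + nContinuous
  if (n < 2) rsError("invalid_scenario", "n must be >= 2")
  if (p < 1) rsError("invalid_scenario", "at least one covariate is required")
  if (censorRate <= 0 || maxFollowup <= 0) {
    rsError("invalid_scenario", "rates and follow-up must be > 0")
  }
  if (any(binaryPrevalence <= 0 | binaryPrevalence >= 1)) {
    rsError("invalid_scenario", "binary prevalences must lie in (0, 1)")
  }
  if (is.null(treatCoefs)) treatCoefs <- rep(0, p)
  if (length(treatCoefs) != p) {
    rsError("invalid_scenario", "treatCoefs must have one entry per covariate")
  }
  if (is.null(outcomes)) {
    outcomes <- list(list(id = "outcome_1", logRate = log(3e-05),
                          coefs = rep(0, p), gamma0 = 0, gamma1 = 0))
  }
  outcomes <- lapply(outcomes, function(o) {
    o$coefs <- o$coefs %||% rep(0, p)
    o$gamma0 <- o$gamma0 %||% 0
    o$gamma1 <- o$gamma1 %||% 0
    if (length(o$coefs) != p) {
      rsError("invalid_scenario", "outcome coefs must have one entry per covariate")
    }
    if (is.null(o$id) || is.null(o$logRate)) {
      rsError("invalid_scenario", "each outcome needs an id and a logRate")
    }
    o
  })
  structure(
    list(n = n, binaryPrevalence = binaryPrevalence, nContinuous = nContinuous,
         p = p, treatIntercept = treatIntercept, treatCoefs = treatCoefs,
         outcomes = outcomes, censorRate = censorRate, maxFollowup = maxFollowup,
         nNegativeControls = nNegativeControls, ncLogRateRange = ncLogRateRange,
         ncCoefSd = ncCoefSd, ncBias = ncBias,
         unmeasuredAssignmentCoef = unmeasuredAssignmentCoef,
         priorEventProb = priorEventProb, seed = as.integer(seed)),
    class = "simulationScenario"
  )
}

#' @export
print.simulationScenario <- function(x, ...) {
  cat("Simulation scenario: n =", x$n, ",", length(x$binaryPrevalence),
      "binary +", x$nContinuous, "continuous covariates,",
      length(x$outcomes), "outcome(s),", x$nNegativeControls,
      "negative controls, seed", x$seed, "\n")
  invisible(x)
}

drawCovariates <- function(scenario, n, seed) {
  nb <- length(scenario$binaryPrevalence)
  withSeed(seed, {
    cols <- vector("list", scenario$p)
    for (j in seq_len(nb)) {
      cols[[j]] <- stats::rbinom(n, 1, scenario$binaryPrevalence[j])
    }
    for (j in seq_len(scenario$nContinuous)) {
      cols[[nb + j]] <- stats::rnorm(n)
    }
    X <- do.call(cbind, cols)
    colnames(X) <- paste0("x", seq_len(scenario$p))
    X
  })
}

outcomeLinpred <- function(o, X) {
  as.vector(X %*% o$coefs)
}

#' Simulate a confounded comparative cohort
#'
#' @param scenario A [simulationScenario()].
#' @param seed Optional override of the scenario seed.
#' @return An object of class `simulatedStudy`: `cohorts` (cohort table with
#'   covariate columns), `outcomes` (outcome event table), the scenario, and
#'   the hidden unmeasured confounder draws (`unmeasured`, not part of the
#'   observable data).
#' @export
simulateCohort <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "simulationScenario"))
  seed <- seed %||% scenario$seed
  n <- scenario$n

  X <- drawCovariates(scenario, n, substreamSeed(seed, "covariates"))
  u <- withSeed(substreamSeed(seed, "unmeasured"), stats::rnorm(n))

  lpTreat <- scenario$treatIntercept + as.vector(X %*% scenario$treatCoefs) +
    scenario$unmeasuredAssignmentCoef * u
  z <- withSeed(substreamSeed(seed, "assignment"),
                stats::rbinom(n, 1, stats::plogis(lpTreat)))
  if (min(sum(z), n - sum(z)) == 0) {
    rsWarning("arm_degenerate", "all subjects assigned to a single arm")
  }

  obsEnd <- withSeed(substreamSeed(seed, "censoring"), {
    pmax(1, ceiling(pmin(stats::rexp(n, scenario$censorRate), scenario$maxFollowup)))
  })

  ids <- sprintf("s%06d", seq_len(n))
  cohorts <- data.frame(
    subject_id = ids,
    arm = ifelse(z == 1, "target", "comparator"),
    obs_end = obsEnd,
    stringsAsFactors = FALSE
  )
  cohorts <- cbind(cohorts, as.data.frame(X))

  rows <- list()
  for (j in seq_along(scenario$outcomes)) {
    o <- scenario$outcomes[[j]]
    lp <- outcomeLinpred(o, X)
    gam <- o$gamma0 + o$gamma1 * lp
    rate <- exp(o$logRate + lp + z * gam)
    ev <- withSeed(substreamSeed(seed, "outcomes", j), {
      t <- stats::rexp(n, rate)
      hist <- if (scenario$priorEventProb > 0) {
        stats::rbinom(n, 1, scenario$priorEventProb) == 1
      } else {
        rep(FALSE, n)
      }
      histTime <- -ceiling(stats::runif(n, 0, 730))
      list(t = t, hist = hist, histTime = histTime)
    })
    keep <- ev$t <= scenario$maxFollowup
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = ids[keep], outcome_id = o$id,
      event_time = ceiling(ev$t[keep]), stringsAsFactors = FALSE
    )
    if (any(ev$hist)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = ids[ev$hist], outcome_id = o$id,
        event_time = ev$histTime[ev$hist], stringsAsFactors = FALSE
      )
    }
  }
  outcomeTable <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(subject_id = character(), outcome_id = character(),
               event_time = numeric())
  }

  structure(
    list(cohorts = cohorts, outcomes = outcomeTable,
         scenario = scenario, seed = seed, unmeasured = u),
    class = "simulatedStudy"
  )
}

#' @export
print.simulatedStudy <- function(x, ...) {
  cat("Simulated study: n =", nrow(x$cohorts), "subjects,",
      nrow(x$outcomes), "outcome records, seed", x$seed, "\n")
  invisible(x)
}

#' Simulate negative-control outcomes
#'
#' Generates event records for `nNegativeControls` outcomes whose hazards
#' depend on the measured covariates (and, when `ncBias != 0`, the unmeasured
#' confounder) but have treatment coefficient exactly 0, so their true hazard
#' ratio is 1.  Outcome ids live in the reserved `nc_*` namespace.
#'
#' @param scenario A [simulationScenario()] with `nNegativeControls >= 2`.
#' @param study The [simulateCohort()] result for the same scenario.
#' @param seed Optional seed override (defaults to the study seed).
#' @return An outcome table (`subject_id`, `outcome_id`, `event_time`).
#' @export
simulateNegativeControls <- function(scenario, study, seed = NULL) {
  stopifnot(inherits(scenario, "simulationScenario"),
            inherits(study, "simulatedStudy"))
  k <- scenario$nNegativeControls
  if (k < 2) rsError("invalid_scenario", "nNegativeControls must be >= 2")
  seed <- seed %||% study$seed
  X <- covariateMatrix(study$cohorts)
  n <- nrow(X)

  rows <- vector("list", k)
  for (i in seq_len(k)) {
    rows[[i]] <- withSeed(substreamSeed(seed, "controls", i), {
      lr <- stats::runif(1, scenario$ncLogRateRange[1], scenario$ncLogRateRange[2])
      b <- stats::rnorm(scenario$p, 0, scenario$ncCoefSd)
      rate <- exp(lr + as.vector(X %*% b) + scenario$ncBias * study$unmeasured)
      t <- stats::rexp(n, rate)
      keep <- t <= scenario$maxFollowup
      data.frame(subject_id = rownames(X)[keep],
                 outcome_id = sprintf("nc_%03d", i),
                 event_time = ceiling(t[keep]), stringsAsFactors = FALSE)
    })
  }
  do.call(rbind, rows)
}

#' Large-sample ground-truth effects per risk group
#'
#' Monte-Carlo oracle: draws a large covariate sample, computes each
#' subject's event probability at the horizon under both arms from the
#' closed-form exponential survival `S_z(h) = exp(-h * rate_z)`, groups
#' subjects by their treatment-free mixture risk `(p1 + p0) / 2` (absolute
#' thresholds or quantiles), and reports per group the true event
#' probabilities, the true risk difference `p0 - p1` (positive favours the
#' target arm) and the true marginal log hazard ratio
#' `log(log(mean S1) / log(mean S0))` with Monte-Carlo standard errors.
#'
#' @param scenario A [simulationScenario()].
#' @param thresholds Strictly increasing absolute risk cutpoints, or `NULL`.
#' @param quantiles Number of quantile groups when `thresholds` is `NULL`.
#' @param outcomeId Which scenario outcome to evaluate (default: first).
#' @param horizon Horizon in days.
#' @param nMc Monte-Carlo sample size (default 1e6).
#' @param seed Seed for the oracle draw (independent of cohort draws).
#' @return A data frame with one row per risk group plus an overall row.
#' @export
trueMarginalEffects <- function(scenario, thresholds = NULL, quantiles = 3,
                                outcomeId = NULL, horizon = 730,
                                nMc = 1e6, seed = NULL) {
  stopifnot(inherits(scenario, "simulationScenario"))
  seed <- seed %||% scenario$seed
  oid <- outcomeId %||% scenario$outcomes[[1]]$id
  o <- NULL
  for (oo in scenario$outcomes) if (identical(oo$id, oid)) o <- oo
  if (is.null(o)) rsError("unknown_outcome", paste("no scenario outcome", oid))

  X <- drawCovariates(scenario, nMc, substreamSeed(seed, "oracle"))
  lp <- outcomeLinpred(o, X)
  gam <- o$gamma0 + o$gamma1 * lp
  rate0 <- exp(o$logRate + lp)
  rate1 <- exp(o$logRate + lp + gam)
  p0 <- 1 - exp(-rate0 * horizon)
  p1 <- 1 - exp(-rate1 * horizon)
  riskMix <- (p0 + p1) / 2

  if (is.null(thresholds)) {
    thresholds <- unique(stats::quantile(riskMix, seq_len(quantiles - 1) / quantiles))
  }
  grp <- findInterval(riskMix, thresholds) + 1L
  k <- length(thresholds) + 1L

  summarise <- function(idx, label) {
    m0 <- mean(p0[idx]); m1 <- mean(p1[idx])
    s0 <- 1 - m0; s1 <- 1 - m1
    data.frame(
      scope = label, n = length(idx),
      p_target = m1, p_comparator = m0,
      rd = m0 - m1,
      rd_mc_se = sqrt(stats::var(p0[idx] - p1[idx]) / length(idx)),
      log_hr = log(log(s1) / log(s0)),
      hr = log(s1) / log(s0),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(seq_len(k), function(g) {
    summarise(which(grp == g), sprintf("RG-%d", g))
  }))
  out <- rbind(summarise(seq_len(nMc), "overall"), out)
  attr(out, "thresholds") <- thresholds
  out
}
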