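# Step-5 orchestration: the full pipeline from one configuration, and tidy
# table output with provenance headers.

#' Configure a full risk-stratified study
#'
#' Inputs are either a [simulationScenario()] or a pair of cohort/outcome
#' files.  The configuration covers every pipeline stage: population
#' construction, the global 1:1 propensity match for risk-model
#' development, the outcome-risk model and risk grouping, within-group
#' propensity estimation, stratified effect estimation and the diagnostic
#' gates.
#'
#' @param scenario A `simulationScenario`, or `NULL` to read files.
#' @param cohortsFile,outcomesFile Delimited input tables (when `scenario`
#'   is `NULL`).
#' @param spec A [studySpec()]; when `NULL` and a scenario is given, a spec
#'   covering the scenario outcomes with default horizon/lookback is built.
#' @param riskOutcomeId Outcome used for the risk model (default: first
#'   outcome in the spec).
#' @param riskThresholds Absolute risk-group cutpoints, or `NULL`.
#' @param riskQuantiles Number of quantile risk groups when
#'   `riskThresholds` is `NULL` (default 3).
#' @param kStrata,folds,pool,balanceThreshold,overlapFloor See
#'   [estimationConfig()].
#' @param caliper,caliperScale See [match1to1()].
#' @param includeControls Whether to analyse `nc_*` outcomes and fit the
#'   systematic-error calibration model (default `TRUE` when present).
#' @param seed Master seed for every stochastic stage.
#' @return A list of class `studyConfig`.
#' @export
studyConfig <- function(scenario = NULL, cohortsFile = NULL,
                        outcomesFile = NULL, spec = NULL,
                        riskOutcomeId = NULL, riskThresholds = NULL,
                        riskQuantiles = 3, kStrata = 5, folds = 3,
                        caliper = 0.2, caliperScale = "std_logit",
                        pool = "ivw", balanceThreshold = 0.1,
                        overlapFloor = 20, includeControls = TRUE,
                        seed = 1) {
  if (is.null(scenario) && (is.null(cohortsFile) || is.null(outcomesFile))) {
    rsError("invalid_config",
            "either a scenario or cohort/outcome files must be given")
  }
  structure(
    list(scenario = scenario, cohortsFile = cohortsFile,
         outcomesFile = outcomesFile, spec = spec,
         riskOutcomeId = riskOutcomeId, riskThresholds = riskThresholds,
         riskQuantiles = riskQuantiles, kStrata = kStrata, folds = folds,
         caliper = caliper, caliperScale = caliperScale, pool = pool,
         balanceThreshold = balanceThreshold, overlapFloor = overlapFloor,
         includeControls = includeControls, seed = as.integer(seed)),
    class = "studyConfig"
  )
}

#' Read a study configuration from YAML
#'
#' Top-level keys mirror the [studyConfig()] arguments; `spec:` holds
#' [studySpec()] fields and `scenario:` holds [simulationScenario()] fields.
#'
#' @param path YAML file path.
#' @return A `studyConfig`.
#' @export
readStudyConfig <- function(path) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 parses a bare key `n:` as boolean FALSE; map it back
  fixNKey <- function(l) {
    names(l)[names(l) %in% c("FALSE", "no")] <- "n"
    l
  }
  spec <- if (!is.null(y$spec)) do.call(studySpec, y$spec) else NULL
  scenario <- if (!is.null(y$scenario)) {
    sc <- fixNKey(y$scenario)
    if (!is.null(sc$outcomes)) {
      sc$outcomes <- lapply(sc$outcomes, function(o) {
        o$coefs <- unlist(o$coefs)
        o
      })
    }
    if (!is.null(sc$binaryPrevalence)) sc$binaryPrevalence <- unlist(sc$binaryPrevalence)
    if (!is.null(sc$treatCoefs)) sc$treatCoefs <- unlist(sc$treatCoefs)
    do.call(simulationScenario, sc)
  } else {
    NULL
  }
  args <- y[setdiff(names(y), c("spec", "scenario"))]
  args$spec <- spec
  args$scenario <- scenario
  do.call(studyConfig, args)
}

configHash <- function(config) {
  # provenance hash of the canonical JSON serialization
  ser <- jsonlite::serializeJSON(unclass(config))
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(ser), f)
  unname(tools::md5sum(f))
}

#' Run the full five-step study
#'
#' Executes: population construction with prior-outcome exclusion -> global
#' propensity model and 1:1 match -> outcome-risk model on the matched
#' subset -> risk-group assignment -> per-risk-group propensity
#' stratification and pooled effect estimation (with diagnostics gates) ->
#' negative-control systematic-error calibration.  Fully deterministic
#' given the config seed.
#'
#' @param config A [studyConfig()].
#' @param verbose Emit per-stage progress messages.
#' @return An object of class `studyReport`: the main `results` grid, the
#'   control results and calibration models per scope, risk model and its
#'   performance table, diagnostics, and provenance (config hash, seed,
#'   package version).
#' @export
runStudy <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "studyConfig"))
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed

  # -- data ----------------------------------------------------------------
  if (!is.null(config$scenario)) {
    scenario <- config$scenario
    study <- simulateCohort(scenario, seed = seed)
    cohorts <- study$cohorts
    outcomes <- study$outcomes
    mainIds <- vapply(scenario$outcomes, `[[`, "", "id")
    ncIds <- character(0)
    if (config$includeControls && scenario$nNegativeControls >= 2) {
      nc <- simulateNegativeControls(scenario, study)
      outcomes <- rbind(outcomes, nc)
      ncIds <- sort(unique(nc$outcome_id))
    }
  } else {
    cohorts <- readCohortTable(config$cohortsFile)
    outcomes <- readOutcomeTable(config$outcomesFile)
    allIds <- sort(unique(outcomes$outcome_id))
    ncIds <- if (config$includeControls) grep("^nc_", allIds, value = TRUE) else character(0)
    mainIds <- setdiff(allIds, ncIds)
  }
  spec <- config$spec %||% studySpec(outcomeIds = c(mainIds, ncIds))
  if (!all(c(mainIds, ncIds) %in% spec$outcomeIds)) {
    spec$outcomeIds <- union(spec$outcomeIds, c(mainIds, ncIds))
  }
  say("building study population (%d subjects, %d outcome records)",
      nrow(cohorts), nrow(outcomes))
  pop <- buildStudyPopulation(cohorts, outcomes, spec)

  # -- global PS match + risk model ---------------------------------------
  riskOutcome <- config$riskOutcomeId %||% mainIds[1]
  say("global propensity model + 1:1 match (caliper %.2g, %s scale)",
      config$caliper, config$caliperScale)
  psGlobal <- fitPropensity(pop, folds = config$folds,
                            seed = substreamSeed(seed, "folds", 1000L))
  match <- match1to1(psGlobal, caliper = config$caliper,
                     caliperScale = config$caliperScale, seed = seed)
  say("matched %d pairs; fitting risk model for '%s'",
      nrow(match$pairs), riskOutcome)
  riskModel <- fitRiskModel(pop, riskOutcome,
                            subjectIds = matchedSubjects(match),
                            folds = config$folds, seed = seed)
  risks <- predictRisk(riskModel, pop)
  riskGroups <- if (!is.null(config$riskThresholds)) {
    assignRiskGroups(risks, thresholds = config$riskThresholds)
  } else {
    assignRiskGroups(risks, quantiles = config$riskQuantiles)
  }
  performance <- riskModelPerformance(riskModel, pop, matchedSubjects(match))

  # -- estimation ----------------------------------------------------------
  estConfig <- estimationConfig(
    kStrata = config$kStrata, folds = config$folds, seed = seed,
    pool = config$pool, balanceThreshold = config$balanceThreshold,
    overlapFloor = config$overlapFloor
  )
  say("estimating effects: %d outcomes x (%d risk groups + overall)",
      length(c(mainIds, ncIds)), nlevels(riskGroups$group))
  results <- estimateEffects(pop, riskGroups, config = estConfig,
                             outcomeIds = c(mainIds, ncIds))
  mainResults <- results[results$outcome_id %in% mainIds, , drop = FALSE]
  ncResults <- results[results$outcome_id %in% ncIds, , drop = FALSE]

  # -- negative-control calibration per scope ------------------------------
  calibration <- list()
  if (length(ncIds) >= 2) {
    for (scope in unique(ncResults$scope)) {
      rr <- ncResults[ncResults$scope == scope, ]
      if (sum(is.finite(rr$log_hr)) >= 2) {
        calibration[[scope]] <- fitNullDistribution(rr$log_hr, rr$se_log_hr)
      }
    }
    cal <- do.call(rbind, lapply(seq_len(nrow(mainResults)), function(i) {
      m <- calibration[[mainResults$scope[i]]]
      if (is.null(m) || !is.finite(mainResults$log_hr[i])) {
        return(data.frame(cal_log_hr = NA_real_, cal_lo = NA_real_,
                          cal_hi = NA_real_, cal_p = NA_real_))
      }
      ci <- calibratedInterval(mainResults$log_hr[i], mainResults$se_log_hr[i], m)
      ci[, c("cal_log_hr", "cal_lo", "cal_hi", "cal_p")]
    }))
    mainResults <- cbind(mainResults, cal)
  }

  structure(
    list(
      results = mainResults, control_results = ncResults,
      calibration = calibration, risk_model = riskModel,
      risk_groups = riskGroups, performance = performance,
      match = match, diagnostics = resultDiagnostics(results),
      components = effectComponents(results),
      provenance = list(config_hash = configHash(config), seed = seed,
                        package_version = as.character(utils::packageVersion("RiskStratEffects")),
                        timestamp = format(Sys.time(), tz = "UTC"))
    ),
    class = "studyReport"
  )
}

#' @export
print.studyReport <- function(x, ...) {
  cat("Risk-stratified study report (seed", x$provenance$seed, ")\n")
  print(x$results[, c("scope", "outcome_id", "hr", "hr_lo", "hr_hi",
                      "rd", "rd_lo", "rd_hi", "suppressed")],
        row.names = FALSE, digits = 3)
  if (length(x$calibration)) {
    ov <- x$calibration[["overall"]]
    if (!is.null(ov)) {
      cat(sprintf("Systematic error (overall): mu = %.3f, sigma = %.3f from %d controls\n",
                  ov$mu, ov$sigma, ov$n))
    }
  }
  invisible(x)
}

#' Pool negative-control components across risk groups
#'
#' For each outcome, inverse-variance pools the per-stratum Cox components
#' of all risk-group scopes (excluding the overall scope) into a single
#' within-risk-group-adjusted estimate — the estimate whose confidence
#' interval is checked against the true null for negative controls.
#'
#' @param results A `resultSet` from [estimateEffects()], or a per-stratum
#'   component table such as `studyReport$components`.
#' @param outcomeIds Outcomes to pool (default: all present).
#' @return Data frame: `outcome_id`, `log_hr`, `se`, `lo`, `hi`, `k`.
#' @export
poolAcrossRiskGroups <- function(results, outcomeIds = NULL) {
  comp <- effectComponents(results) %||% results
  comp <- comp[comp$scope != "overall", , drop = FALSE]
  outcomeIds <- outcomeIds %||% unique(comp$outcome_id)
  rows <- lapply(outcomeIds, function(oid) {
    cc <- comp[comp$outcome_id == oid, ]
    p <- poolRelative(cc$log_hr, cc$se_log_hr)
    data.frame(outcome_id = oid,
               log_hr = p$log_hr, se = p$se,
               lo = if (p$estimable) p$log_hr - 1.96 * p$se else NA_real_,
               hi = if (p$estimable) p$log_hr + 1.96 * p$se else NA_real_,
               k = p$k, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write the study report as tidy delimited tables
#'
#' Emits the effect grid (relative and absolute scale per risk group and
#' overall), the per-stratum components, the diagnostics tables behind the
#' balance / overlap / negative-control figures, the calibration
#' parameters, and the risk-model performance table.  Every file carries a
#' provenance header (`# config_hash=...`, `# seed=...`) and re-rendering
#' the same report produces byte-identical files.
#'
#' @param report A `studyReport`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
renderTables <- function(report, dir) {
  stopifnot(inherits(report, "studyReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  header <- c(
    sprintf("# config_hash=%s", report$provenance$config_hash),
    sprintf("# seed=%d", report$provenance$seed),
    sprintf("# package_version=%s", report$provenance$package_version)
  )
  writeOne <- function(df, name) {
    path <- file.path(dir, name)
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
    path
  }
  paths <- c(
    writeOne(report$results, "effects.csv"),
    writeOne(report$components, "effect_components.csv"),
    writeOne(report$performance, "risk_model_performance.csv")
  )
  if (nrow(report$control_results)) {
    paths <- c(paths, writeOne(report$control_results, "negative_controls.csv"))
  }
  bal <- do.call(rbind, lapply(names(report$diagnostics), function(scope) {
    b <- report$diagnostics[[scope]]$balance
    if (is.null(b)) return(NULL)
    cbind(scope = scope, b$table)
  }))
  if (!is.null(bal)) paths <- c(paths, writeOne(bal, "balance.csv"))
  ovl <- data.frame(
    scope = names(report$diagnostics),
    overlap_pct = vapply(report$diagnostics, function(d) d$overlap %||% NA_real_, 0),
    gate = vapply(report$diagnostics, function(d) isTRUE(d$gate), TRUE),
    stringsAsFactors = FALSE
  )
  paths <- c(paths, writeOne(ovl, "overlap.csv"))
  if (length(report$calibration)) {
    calDf <- do.call(rbind, lapply(names(report$calibration), function(scope) {
      m <- report$calibration[[scope]]
      data.frame(scope = scope, mu = m$mu, sigma = m$sigma, n_controls = m$n,
                 stringsAsFactors = FALSE)
    }))
    paths <- c(paths, writeOne(calDf, "calibration.csv"))
  }
  grp <- as.data.frame(table(report$risk_groups$group))
  names(grp) <- c("group", "n")
  paths <- c(paths, writeOne(grp, "risk_group_sizes.csv"))
  invisible(paths)
}

#' Read back a rendered result table
#'
#' Parses a table written by [renderTables()], skipping the provenance
#' header.
#'
#' @param path File path.
#' @return A data frame.
#' @export
readResultTable <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
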