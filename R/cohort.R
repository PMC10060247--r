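# Study-design data model: study specification, cohort/outcome tables, and
# construction of analysis-ready time-to-event study populations.

#' Define a comparative cohort study specification
#'
#' A study compares a target treatment cohort against a comparator cohort with
#' respect to one or more outcomes, within a fixed time-at-risk horizon
#' starting at treatment initiation (the index date).  Subjects with a record
#' of an outcome prior to index are excluded from that outcome's analysis set.
#'
#' @param treatmentId Label of the target treatment cohort.
#' @param comparatorId Label of the comparator treatment cohort.
#' @param outcomeIds Character vector of outcome identifiers (non-empty,
#'   unique).
#' @param lookback Minimum baseline observation window before index, in days.
#'   Used when `priorExclusionWindow = "lookback"`.
#' @param horizon Time-at-risk horizon in days after index (default two
#'   years).  Follow-up is truncated at this horizon (intention-to-treat).
#' @param priorExclusionWindow Either `"all"` (exclude subjects with an
#'   outcome record at any time at or before index; the default) or
#'   `"lookback"` (only records inside the lookback window trigger
#'   exclusion).
#'
#' @return An object of class `studySpec`.
#' @export
studySpec <- function(treatmentId = "target",
                      comparatorId = "comparator",
                      outcomeIds = "outcome_1",
                      lookback = 365,
                      horizon = 730,
                      priorExclusionWindow = c("all", "lookback")) {
  priorExclusionWindow <- match.arg(priorExclusionWindow)
  if (identical(treatmentId, comparatorId)) {
    rsError("invalid_spec", "treatmentId and comparatorId must differ")
  }
  if (length(outcomeIds) == 0 || anyDuplicated(outcomeIds) > 0) {
    rsError("invalid_spec", "outcomeIds must be non-empty and unique")
  }
  if (!is.numeric(lookback) || lookback <= 0) {
    rsError("invalid_spec", "lookback must be > 0")
  }
  if (!is.numeric(horizon) || horizon <= 0) {
    rsError("invalid_spec", "horizon must be > 0")
  }
  structure(
    list(
      treatmentId = treatmentId,
      comparatorId = comparatorId,
      outcomeIds = as.character(outcomeIds),
      lookback = lookback,
      horizon = horizon,
      priorExclusionWindow = priorExclusionWindow
    ),
    class = "studySpec"
  )
}

#' @export
print.studySpec <- function(x, ...) {
  cat("Study specification\n")
  cat("  target:     ", x$treatmentId, "\n")
  cat("  comparator: ", x$comparatorId, "\n")
  cat("  outcomes:   ", paste(x$outcomeIds, collapse = ", "), "\n")
  cat("  horizon:    ", x$horizon, "days; lookback:", x$lookback, "days\n")
  cat("  prior-outcome exclusion window:", x$priorExclusionWindow, "\n")
  invisible(x)
}

.cohortReserved <- c("subject_id", "arm", "obs_end")

# Extract the covariate matrix (all non-reserved numeric columns) from a
# cohort table, rownames = subject ids.
covariateMatrix <- function(cohorts) {
  covCols <- setdiff(names(cohorts), .cohortReserved)
  x <- as.matrix(cohorts[, covCols, drop = FALSE])
  if (length(covCols) && !is.numeric(x)) {
    rsError("invalid_covariates", "covariate columns must be numeric")
  }
  rownames(x) <- cohorts$subject_id
  x
}

validateCohortTable <- function(cohorts) {
  need <- c("subject_id", "arm", "obs_end")
  if (!all(need %in% names(cohorts))) {
    rsError("invalid_cohorts",
            paste("cohort table must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(cohorts$subject_id) > 0) {
    rsError("duplicate_subject", "duplicate subject ids in cohort table")
  }
  if (any(!cohorts$arm %in% c("target", "comparator"))) {
    rsError("invalid_cohorts", "arm must be 'target' or 'comparator'")
  }
  for (a in c("target", "comparator")) {
    if (!any(cohorts$arm == a)) {
      rsError("arm_empty", paste0("cohort arm '", a, "' is empty"))
    }
  }
  if (any(cohorts$obs_end < 0)) {
    rsError("invalid_cohorts", "obs_end must be >= 0")
  }
  invisible(cohorts)
}

#' Build an analysis-ready study population
#'
#' For every outcome in the specification, subjects with an outcome record at
#' or before the index date (time 0) are excluded from that outcome's
#' analysis set; remaining subjects receive a time-to-event
#' `tte = min(first post-index event time, obs_end, horizon)` and an event
#' indicator equal to 1 when the first post-index event occurs at or before
#' both truncation times.  Only the earliest post-index event per subject and
#' outcome is used.
#'
#' @param cohorts Cohort table: a data frame with columns `subject_id`,
#'   `arm` (`"target"`/`"comparator"`), `obs_end` (days of observation after
#'   index) and one numeric column per baseline covariate.
#' @param outcomes Outcome table: a data frame with columns `subject_id`,
#'   `outcome_id`, `event_time` (days relative to index; non-positive times
#'   are medical history).
#' @param spec A [studySpec()].
#'
#' @return An object of class `studyPopulation` with elements `subjects`
#'   (subject_id, arm, obs_end), `covariates` (numeric matrix), `outcomes`
#'   (per outcome id, a data frame `subject_id`, `tte`, `event` over the
#'   analysis set) and `excluded` (per outcome id, the excluded subject ids).
#' @export
buildStudyPopulation <- function(cohorts, outcomes, spec) {
  stopifnot(inherits(spec, "studySpec"))
  cohorts <- as.data.frame(cohorts)
  validateCohortTable(cohorts)
  if (is.null(outcomes) || nrow(outcomes) == 0) {
    outcomes <- data.frame(subject_id = character(), outcome_id = character(),
                           event_time = numeric())
  }
  outcomes <- as.data.frame(outcomes)
  if (!all(c("subject_id", "outcome_id", "event_time") %in% names(outcomes))) {
    rsError("invalid_outcomes",
            "outcome table must have columns subject_id, outcome_id, event_time")
  }
  if (any(!is.finite(outcomes$event_time))) {
    rsError("invalid_outcomes", "event times must be finite")
  }

  subjects <- cohorts[, .cohortReserved]
  X <- covariateMatrix(cohorts)
  horizon <- spec$horizon
  priorFloor <- if (spec$priorExclusionWindow == "all") -Inf else -spec$lookback

  ot <- data.table::as.data.table(outcomes)
  perOutcome <- list()
  excluded <- list()
  for (oid in spec$outcomeIds) {
    oo <- ot[ot$outcome_id == oid, ]
    prior <- unique(oo$subject_id[oo$event_time <= 0 & oo$event_time >= priorFloor])
    prior <- prior[prior %in% subjects$subject_id]
    post <- oo[oo$event_time > 0, ]
    first <- if (nrow(post)) {
      post[, list(first_event = min(event_time)), by = "subject_id"]
    } else {
      data.table::data.table(subject_id = character(), first_event = numeric())
    }

    keep <- subjects[!(subjects$subject_id %in% prior) & subjects$obs_end > 0, ]
    fe <- first$first_event[match(keep$subject_id, first$subject_id)]
    fe[is.na(fe)] <- Inf
    trunc <- pmin(keep$obs_end, horizon)
    event <- as.integer(fe <= trunc)
    tte <- pmin(fe, trunc)
    perOutcome[[oid]] <- data.frame(
      subject_id = keep$subject_id, tte = tte, event = event,
      stringsAsFactors = FALSE
    )
    excluded[[oid]] <- prior
  }

  structure(
    list(subjects = subjects, covariates = X, spec = spec,
         outcomes = perOutcome, excluded = excluded),
    class = "studyPopulation"
  )
}

#' @export
print.studyPopulation <- function(x, ...) {
  cat("Study population:", nrow(x$subjects), "subjects (",
      sum(x$subjects$arm == "target"), "target /",
      sum(x$subjects$arm == "comparator"), "comparator ),",
      ncol(x$covariates), "covariates\n")
  for (oid in names(x$outcomes)) {
    oo <- x$outcomes[[oid]]
    cat(sprintf("  %s: n = %d (excluded %d), events = %d\n",
                oid, nrow(oo), length(x$excluded[[oid]]), sum(oo$event)))
  }
  invisible(x)
}

# Restrict a study population to a set of subject ids, preserving per-outcome
# tte/event values.
subsetPopulation <- function(pop, subjectIds) {
  keep <- pop$subjects$subject_id %in% subjectIds
  out <- pop
  out$subjects <- pop$subjects[keep, , drop = FALSE]
  out$covariates <- pop$covariates[keep, , drop = FALSE]
  out$outcomes <- lapply(pop$outcomes, function(oo) {
    oo[oo$subject_id %in% subjectIds, , drop = FALSE]
  })
  out
}

#' Filter a study population by a covariate condition
#'
#' Returns the sub-population whose covariates satisfy a predicate, e.g.
#' `"prior_cvd == 0"`; per-outcome time-to-event fields are unchanged.  Used
#' for sensitivity analyses in clinically defined subgroups.
#'
#' @param pop A `studyPopulation`.
#' @param predicate A one-sided formula (`~ prior_cvd == 0`) or a string
#'   (`"prior_cvd == 0"`) referencing covariate names.
#' @return The filtered `studyPopulation`.
#' @export
filterSubgroup <- function(pop, predicate) {
  stopifnot(inherits(pop, "studyPopulation"))
  expr <- if (inherits(predicate, "formula")) {
    predicate[[length(predicate)]]
  } else {
    str2lang(as.character(predicate))
  }
  vars <- all.vars(expr)
  unknown <- setdiff(vars, colnames(pop$covariates))
  if (length(unknown)) {
    rsError("unknown_covariate",
            paste("predicate references unknown covariate(s):",
                  paste(unknown, collapse = ", ")))
  }
  keep <- eval(expr, envir = as.data.frame(pop$covariates))
  if (!is.logical(keep) || length(keep) != nrow(pop$subjects)) {
    rsError("invalid_predicate", "predicate must evaluate to one logical per subject")
  }
  keep[is.na(keep)] <- FALSE
  subsetPopulation(pop, pop$subjects$subject_id[keep])
}

#' Read / write cohort and outcome tables
#'
#' Tables are stored as comma-separated text with a header row (UTF-8), or as
#' Parquet when the file extension is `.parquet` and the `arrow` package is
#' available.
#'
#' @param path File path.
#' @param x Table to write.
#' @return `readCohortTable()`/`readOutcomeTable()` return data frames.
#' @export
readCohortTable <- function(path) {
  readDelimited(path)
}

#' @rdname readCohortTable
#' @export
writeCohortTable <- function(x, path) {
  writeDelimited(x, path)
}

#' @rdname readCohortTable
#' @export
readOutcomeTable <- function(path) {
  readDelimited(path)
}

#' @rdname readCohortTable
#' @export
writeOutcomeTable <- function(x, path) {
  writeDelimited(x, path)
}

readDelimited <- function(path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      rsError("format_unavailable", "parquet support requires the 'arrow' package")
    }
    return(as.data.frame(arrow::read_parquet(path)))
  }
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}

writeDelimited <- function(x, path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      rsError("format_unavailable", "parquet support requires the 'arrow' package")
    }
    arrow::write_parquet(x, path)
  } else {
    utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
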