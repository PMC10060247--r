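# Outcome-risk prediction: LASSO logistic model fitted on the 1:1
# propensity-matched subset, per-subject predicted risk, discrimination
# (c-statistic) in the four reporting populations, and risk-group assignment.

#' Fit the outcome-risk prediction model
#'
#' Fits an L1-penalized logistic regression of "event within the horizon"
#' on the full covariate set, by default restricted to the propensity
#' score-matched subset so that the model is not fitted differentially
#' between treatment arms (which would introduce spurious interactions with
#' treatment).  The penalty is selected by k-fold cross-validated deviance
#' on a logarithmic grid; fold assignment is seeded and stratified by
#' outcome so folds never end up single-class.
#'
#' @param pop A `studyPopulation`.
#' @param outcomeId Which outcome to model.
#' @param subjectIds Optional subject ids to fit on (typically
#'   `matchedSubjects(match)`); `NULL` fits on the full analysis set.
#' @param folds Number of CV folds (default 3).
#' @param seed Seed for fold assignment.
#' @param lambda Optional fixed penalty overriding CV selection.
#' @return An object of class `riskModel` with the intercept, the sparse
#'   nonzero coefficients, the selected lambda, and the cross-validated
#'   c-statistic computed from prevalidated out-of-fold predictions.
#' @export
fitRiskModel <- function(pop, outcomeId, subjectIds = NULL, folds = 3,
                         seed = 1, lambda = NULL) {
  stopifnot(inherits(pop, "studyPopulation"))
  an <- pop$outcomes[[outcomeId]]
  if (is.null(an)) rsError("unknown_outcome", paste("no outcome", outcomeId))
  if (!is.null(subjectIds)) {
    an <- an[an$subject_id %in% subjectIds, , drop = FALSE]
  }
  if (nrow(an) == 0 || sum(an$event) == 0) {
    rsError("no_events", "no outcome events in the fitting subset")
  }
  X <- pop$covariates[match(an$subject_id, rownames(pop$covariates)), ,
                      drop = FALSE]
  fit <- fitLassoLogistic(X, an$event, folds = folds, seed = seed,
                          lambda = lambda)
  cvC <- if (!is.null(fit$preval)) {
    concordance(stats::plogis(fit$preval), an$event)
  } else {
    NULL
  }
  structure(
    list(intercept = fit$intercept, coefficients = fit$coefficients,
         lambda = fit$lambda, outcome_id = outcomeId,
         horizon = pop$spec$horizon,
         fit_population = if (is.null(subjectIds)) "entire" else "matched",
         n = nrow(an), events = sum(an$event),
         cv_c = cvC, folds = folds, seed = seed),
    class = "riskModel"
  )
}

#' @export
print.riskModel <- function(x, ...) {
  cat(sprintf(
    "Risk model for '%s' (%d-day horizon): %d subjects, %d events,\n",
    x$outcome_id, x$horizon, x$n, x$events))
  cat(sprintf("  %d nonzero coefficients at lambda = %.5g (%s population)\n",
              length(x$coefficients), x$lambda, x$fit_population))
  if (!is.null(x$cv_c)) {
    cat(sprintf("  cross-validated c-statistic: %.3f (%.3f, %.3f)\n",
                x$cv_c$c, x$cv_c$ci[1], x$cv_c$ci[2]))
  }
  invisible(x)
}

#' Predict per-subject outcome risk
#'
#' `risk = expit(intercept + coefficients . x)`; covariates missing from the
#' data are treated as 0 (absence semantics of sparse features).
#'
#' @param model A `riskModel`.
#' @param pop A `studyPopulation` (or a covariate matrix with column names).
#' @return A named numeric vector of risks in (0, 1), one per subject.
#' @export
predictRisk <- function(model, pop) {
  stopifnot(inherits(model, "riskModel"))
  X <- if (inherits(pop, "studyPopulation")) pop$covariates else as.matrix(pop)
  lp <- sparseLinpred(model$intercept, model$coefficients, X)
  r <- stats::plogis(lp)
  names(r) <- rownames(X)
  r
}

#' Concordance statistic (c-statistic) with DeLong confidence interval
#'
#' The probability that a randomly chosen event subject is ranked above a
#' randomly chosen non-event subject, counting ties as 1/2; the standard
#' error uses the DeLong asymptotic variance of the placement values.
#'
#' @param risks Numeric predictions.
#' @param labels 0/1 outcome labels.
#' @param level Confidence level (default 0.95).
#' @return A list with `c`, `se`, `ci` (clipped to `[0, 1]`), and the class
#'   counts `n1`, `n0`.
#' @export
concordance <- function(risks, labels, level = 0.95) {
  labels <- as.integer(labels)
  pos <- risks[labels == 1]
  neg <- risks[labels == 0]
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) {
    rsError("undefined_c", "both classes must be present")
  }
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  # DeLong placement values
  v10 <- (r[seq_len(m)] - rank(pos, ties.method = "average")) / n
  v01 <- 1 - (r[m + seq_len(n)] - rank(neg, ties.method = "average")) / m
  s2 <- 0
  if (m > 1) s2 <- s2 + stats::var(v10) / m
  if (n > 1) s2 <- s2 + stats::var(v01) / n
  se <- sqrt(s2)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci <- c(max(0, auc - zq * se), min(1, auc + zq * se))
  list(c = auc, se = se, ci = ci, n1 = m, n0 = n)
}

#' Discrimination of the risk model in the reporting populations
#'
#' Evaluates the c-statistic of a fitted risk model in the matched subset
#' (development set), the treatment cohort, the comparator cohort, and the
#' entire study population, each over that outcome's analysis set.  The
#' matched row is reported twice: apparent (refit predictions on the
#' development data) and cross-validated (prevalidated out-of-fold
#' predictions from model fitting).
#'
#' @param model A `riskModel`.
#' @param pop The `studyPopulation`.
#' @param matchedIds Subject ids of the matched development subset.
#' @return A data frame with columns `population`, `c`, `ci_lo`, `ci_hi`,
#'   `n`, `events`.
#' @export
riskModelPerformance <- function(model, pop, matchedIds) {
  an <- pop$outcomes[[model$outcome_id]]
  risks <- predictRisk(model, pop)
  arm <- pop$subjects$arm[match(an$subject_id, pop$subjects$subject_id)]
  sets <- list(
    matched = an$subject_id %in% matchedIds,
    treatment = arm == "target",
    comparator = arm == "comparator",
    entire = rep(TRUE, nrow(an))
  )
  rows <- lapply(names(sets), function(nm) {
    idx <- sets[[nm]]
    cc <- concordance(risks[an$subject_id[idx]], an$event[idx])
    data.frame(population = nm, c = cc$c, ci_lo = cc$ci[1], ci_hi = cc$ci[2],
               n = sum(idx), events = sum(an$event[idx]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(model$cv_c)) {
    out <- rbind(out, data.frame(
      population = "matched_cv", c = model$cv_c$c,
      ci_lo = model$cv_c$ci[1], ci_hi = model$cv_c$ci[2],
      n = model$n, events = model$events, stringsAsFactors = FALSE
    ))
  }
  out
}

#' Assign subjects to risk groups
#'
#' Partitions predicted risks into half-open intervals
#' `[0, t1), [t1, t2), ..., [tk, 1]` labelled `RG-1 ... RG-(k+1)`; a risk
#' exactly equal to a threshold falls in the higher group.  Thresholds can
#' be given absolutely (e.g. the 1% and 1.5% cutoffs of a demonstration
#' study) or derived from risk quantiles.
#'
#' @param risks Named vector of predicted risks (names = subject ids).
#' @param thresholds Strictly increasing cutpoints in (0, 1), or `NULL` to
#'   use quantiles.
#' @param quantiles Number of equal-count groups when `thresholds` is `NULL`.
#' @return An object of class `riskGroupAssignment`: a data frame
#'   (`subject_id`, `risk`, `group`) with the thresholds as an attribute.
#' @export
assignRiskGroups <- function(risks, thresholds = c(0.01, 0.015),
                             quantiles = NULL) {
  if (!is.null(quantiles)) {
    thresholds <- unname(stats::quantile(risks, seq_len(quantiles - 1) / quantiles))
    thresholds <- unique(thresholds)
  }
  if (length(thresholds) == 0 || any(diff(c(0, thresholds, 1)) <= 0)) {
    rsError("bad_thresholds", "thresholds must be strictly increasing in (0, 1)")
  }
  g <- findInterval(risks, thresholds) + 1L
  k <- length(thresholds) + 1L
  out <- data.frame(
    subject_id = names(risks) %||% as.character(seq_along(risks)),
    risk = unname(risks),
    group = factor(sprintf("RG-%d", g), levels = sprintf("RG-%d", seq_len(k))),
    stringsAsFactors = FALSE
  )
  structure(out, thresholds = thresholds, class = c("riskGroupAssignment",
                                                    "data.frame"))
}

#' @export
print.riskGroupAssignment <- function(x, ...) {
  cat("Risk groups (thresholds:",
      paste(signif(attr(x, "thresholds"), 4), collapse = ", "), ")\n")
  print(table(x$group))
  invisible(x)
}
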