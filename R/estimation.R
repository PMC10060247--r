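# Effect estimation: per-stratum Cox hazard ratios and Kaplan-Meier risk
# differences at the horizon, pooled within risk groups (and overall).

#' Cox hazard ratio in one propensity-score stratum
#'
#' Single-covariate Cox proportional-hazards fit of the treatment indicator
#' with Breslow tie handling.  Strata with no events, a single arm, or a
#' monotone partial likelihood are flagged inestimable and excluded from
#' pooling (with the reason recorded).
#'
#' @param tte Time to event or censoring (days, > 0).
#' @param event 0/1 event indicator.
#' @param arm `"target"`/`"comparator"` labels.
#' @return A list: `log_hr`, `se`, counts per arm, `estimable`, `reason`.
#' @export
coxStratumHr <- function(tte, event, arm) {
  z <- as.integer(arm == "target")
  out <- list(
    log_hr = NA_real_, se = NA_real_,
    n = length(tte), n_target = sum(z == 1), n_comparator = sum(z == 0),
    events_target = sum(event[z == 1]), events_comparator = sum(event[z == 0]),
    estimable = FALSE, reason = NA_character_
  )
  if (out$n_target == 0 || out$n_comparator == 0) {
    out$reason <- "single_arm"
    return(out)
  }
  if (sum(event) == 0) {
    out$reason <- "no_events"
    return(out)
  }
  fit <- tryCatch(
    survival::coxph(survival::Surv(tte, event) ~ z, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-09,
                                                      iter.max = 100)),
    warning = function(w) w, error = function(e) e
  )
  if (inherits(fit, "condition")) {
    out$reason <- "nonconverged"
    return(out)
  }
  b <- unname(stats::coef(fit))
  se <- unname(sqrt(diag(fit$var)))
  if (!is.finite(b) || !is.finite(se) || se > 50 || abs(b) > 20) {
    out$reason <- "monotone_likelihood"
    return(out)
  }
  out$log_hr <- b
  out$se <- se
  out$estimable <- TRUE
  out
}

#' Kaplan-Meier risk difference at the horizon in one stratum
#'
#' Computes per-arm Kaplan-Meier survival at the horizon with Greenwood
#' standard errors and returns the risk difference
#' `rd = S_target(h) - S_comparator(h)` (the comparator cumulative
#' incidence minus the target cumulative incidence): positive values favour
#' the target arm.  When the horizon exceeds the last observed time,
#' survival is carried forward from the last event time and the component
#' is flagged `extrapolated`.
#'
#' @inheritParams coxStratumHr
#' @param horizon Evaluation time (days).
#' @return A list: `rd`, `se`, per-arm survival and its SE, `estimable`,
#'   `extrapolated`, `reason`.
#' @export
kmStratumRd <- function(tte, event, arm, horizon) {
  z <- arm == "target"
  out <- list(rd = NA_real_, se = NA_real_,
              s_target = NA_real_, s_comparator = NA_real_,
              se_target = NA_real_, se_comparator = NA_real_,
              n = length(tte), estimable = FALSE,
              extrapolated = FALSE, reason = NA_character_)
  if (sum(z) == 0 || sum(!z) == 0) {
    out$reason <- "single_arm"
    return(out)
  }
  kmArm <- function(idx) {
    f <- survival::survfit(survival::Surv(tte[idx], event[idx]) ~ 1)
    sm <- summary(f, times = horizon, extend = TRUE)
    s <- sm$surv
    se <- sm$std.err
    if (!is.finite(se)) se <- 0
    list(s = s, se = se, last = max(tte[idx]))
  }
  t <- kmArm(z)
  c <- kmArm(!z)
  out$s_target <- t$s; out$se_target <- t$se
  out$s_comparator <- c$s; out$se_comparator <- c$se
  out$rd <- t$s - c$s
  out$se <- sqrt(t$se^2 + c$se^2)
  out$extrapolated <- horizon > max(t$last, c$last)
  out$estimable <- TRUE
  out
}

#' Pool per-stratum relative effects
#'
#' Inverse-variance weighted mean of per-stratum log hazard ratios (the
#' default reading of "averaging over the hazard ratio estimates"); the
#' pooled standard error is `sqrt(1 / sum(w))` and the 95% CI is formed on
#' the log scale and exponentiated.  `"arithmetic_log"` pools with equal
#' weights instead.
#'
#' @param logHrs,ses Per-stratum estimates and standard errors (inestimable
#'   components as `NA`).
#' @param pool `"ivw"` or `"arithmetic_log"`.
#' @return A list: `log_hr`, `se`, `ci` (on the HR scale), `k` components
#'   used, `estimable`.
#' @export
poolRelative <- function(logHrs, ses, pool = c("ivw", "arithmetic_log")) {
  pool <- match.arg(pool)
  ok <- is.finite(logHrs) & is.finite(ses) & ses > 0
  if (!any(ok)) {
    return(list(log_hr = NA_real_, se = NA_real_, ci = c(NA_real_, NA_real_),
                k = 0L, estimable = FALSE))
  }
  x <- logHrs[ok]; s <- ses[ok]
  if (pool == "ivw") {
    w <- 1 / s^2
    est <- sum(w * x) / sum(w)
    se <- sqrt(1 / sum(w))
  } else {
    est <- mean(x)
    se <- sqrt(sum(s^2)) / length(x)
  }
  list(log_hr = est, se = se,
       ci = exp(est + c(-1, 1) * 1.96 * se),
       k = sum(ok), estimable = TRUE)
}

#' Pool per-stratum absolute effects
#'
#' Stratum-size weighted mean of Kaplan-Meier risk differences
#' (approximating the average treatment effect over the risk group), with
#' `se = sqrt(sum((w_i / sum w)^2 se_i^2))` and a Wald 95% CI.
#'
#' @param rds,ses Per-stratum risk differences and standard errors.
#' @param weights Stratum sizes.
#' @return A list: `rd`, `se`, `ci`, `k`, `estimable`.
#' @export
poolAbsolute <- function(rds, ses, weights) {
  ok <- is.finite(rds) & is.finite(ses) & weights > 0
  if (!any(ok)) {
    return(list(rd = NA_real_, se = NA_real_, ci = c(NA_real_, NA_real_),
                k = 0L, estimable = FALSE))
  }
  w <- weights[ok] / sum(weights[ok])
  est <- sum(w * rds[ok])
  se <- sqrt(sum(w^2 * ses[ok]^2))
  list(rd = est, se = se, ci = est + c(-1, 1) * 1.96 * se,
       k = sum(ok), estimable = TRUE)
}

#' Estimation settings
#'
#' @param kStrata Propensity-score strata per risk group (default 5).
#' @param folds CV folds of the propensity LASSO.
#' @param seed Seed for fold assignment.
#' @param pool Relative-effect pooling: `"ivw"` or `"arithmetic_log"`.
#' @param balanceThreshold Post-adjustment SMD gate (rule of thumb 0.1).
#' @param overlapFloor Minimum preference-score overlap percent before a
#'   risk group's results are suppressed (default 20).
#' @param psLambda Optional fixed propensity penalty overriding CV.
#' @return A list of class `estimationConfig`.
#' @export
estimationConfig <- function(kStrata = 5, folds = 3, seed = 1,
                             pool = c("ivw", "arithmetic_log"),
                             balanceThreshold = 0.1, overlapFloor = 20,
                             psLambda = NULL) {
  structure(
    list(kStrata = kStrata, folds = folds, seed = seed,
         pool = match.arg(pool), balanceThreshold = balanceThreshold,
         overlapFloor = overlapFloor, psLambda = psLambda),
    class = "estimationConfig"
  )
}

#' Estimate pooled treatment effects per risk group and overall
#'
#' For each risk group (and for the ungrouped population), fits a
#' within-group propensity model, stratifies into `kStrata` score quintiles,
#' fits a Cox model and a Kaplan-Meier risk difference per stratum and
#' outcome, and pools them (inverse-variance on the log-HR scale;
#' stratum-size weighted for risk differences).  Balance and equipoise
#' diagnostics are evaluated per scope; cells in scopes failing a gate are
#' retained but flagged `suppressed` with a machine-readable reason.
#'
#' @param pop A `studyPopulation`.
#' @param riskGroups A `riskGroupAssignment` (or `NULL` for overall only).
#' @param config An [estimationConfig()].
#' @param outcomeIds Outcomes to estimate (default: all in `pop`).
#' @return A `resultSet`: a tidy data frame with one row per
#'   (scope x outcome), with per-stratum components, diagnostics and
#'   propensity fits attached as attributes.
#' @export
estimateEffects <- function(pop, riskGroups = NULL,
                            config = estimationConfig(),
                            outcomeIds = NULL) {
  stopifnot(inherits(pop, "studyPopulation"))
  outcomeIds <- outcomeIds %||% names(pop$outcomes)
  horizon <- pop$spec$horizon

  scopes <- list(overall = pop$subjects$subject_id)
  if (!is.null(riskGroups)) {
    for (g in levels(riskGroups$group)) {
      scopes[[g]] <- riskGroups$subject_id[riskGroups$group == g]
    }
  }

  rows <- list()
  comps <- list()
  diagnostics <- list()
  for (si in seq_along(scopes)) {
    scope <- names(scopes)[si]
    ids <- scopes[[si]]
    sub <- subsetPopulation(pop, ids)
    if (length(unique(sub$subjects$arm)) < 2 || nrow(sub$subjects) < config$kStrata) {
      diagnostics[[scope]] <- list(ps = NULL, overlap = NA_real_,
                                   balance = NULL, gate = FALSE,
                                   reason = "scope_degenerate")
      for (oid in outcomeIds) {
        rows[[length(rows) + 1L]] <- resultRow(scope, oid, NULL, NULL,
                                               TRUE, "scope_degenerate")
      }
      next
    }
    psr <- fitPropensity(sub, folds = config$folds,
                         seed = substreamSeed(config$seed, "folds", si),
                         lambda = config$psLambda)
    strata <- suppressWarnings(stratifyByPs(psr, k = config$kStrata))
    bal <- evaluateBalance(sub, strata, threshold = config$balanceThreshold)
    ft <- psr$scores$preference[psr$scores$arm == "target"]
    fc <- psr$scores$preference[psr$scores$arm == "comparator"]
    ovl <- overlapFraction(ft, fc)
    gate <- bal$gate && ovl >= config$overlapFloor
    reason <- if (gate) {
      NA_character_
    } else if (!bal$gate) {
      "balance_failed"
    } else {
      "insufficient_overlap"
    }
    diagnostics[[scope]] <- list(ps = psr, overlap = ovl, balance = bal,
                                 gate = gate, reason = reason)

    stratumOf <- strata$stratum
    names(stratumOf) <- strata$subject_id
    armOf <- sub$subjects$arm
    names(armOf) <- sub$subjects$subject_id

    for (oid in outcomeIds) {
      an <- sub$outcomes[[oid]]
      st <- stratumOf[an$subject_id]
      compRows <- list()
      hr <- list(); rd <- list()
      for (s in sort(unique(st))) {
        idx <- which(st == s)
        arm <- armOf[an$subject_id[idx]]
        ch <- coxStratumHr(an$tte[idx], an$event[idx], arm)
        kh <- kmStratumRd(an$tte[idx], an$event[idx], arm, horizon)
        hr[[length(hr) + 1L]] <- ch
        rd[[length(rd) + 1L]] <- kh
        compRows[[length(compRows) + 1L]] <- data.frame(
          scope = scope, outcome_id = oid, stratum = s, n = ch$n,
          n_target = ch$n_target, n_comparator = ch$n_comparator,
          events_target = ch$events_target,
          events_comparator = ch$events_comparator,
          log_hr = ch$log_hr, se_log_hr = ch$se,
          hr_estimable = ch$estimable, hr_reason = ch$reason,
          rd = kh$rd, se_rd = kh$se, rd_estimable = kh$estimable,
          stringsAsFactors = FALSE
        )
      }
      compDf <- do.call(rbind, compRows)
      comps[[length(comps) + 1L]] <- compDf
      pooledHr <- poolRelative(compDf$log_hr, compDf$se_log_hr,
                               pool = config$pool)
      pooledRd <- poolAbsolute(compDf$rd, compDf$se_rd, compDf$n)
      rows[[length(rows) + 1L]] <- resultRow(scope, oid, pooledHr, pooledRd,
                                             !gate, reason,
                                             nTarget = sum(compDf$n_target),
                                             nComparator = sum(compDf$n_comparator),
                                             eventsTarget = sum(compDf$events_target),
                                             eventsComparator = sum(compDf$events_comparator))
    }
  }

  out <- do.call(rbind, rows)
  attr(out, "components") <- if (length(comps)) do.call(rbind, comps) else NULL
  attr(out, "diagnostics") <- diagnostics
  attr(out, "config") <- config
  class(out) <- c("resultSet", "data.frame")
  out
}

resultRow <- function(scope, oid, pooledHr, pooledRd, suppressed, reason,
                      nTarget = NA_integer_, nComparator = NA_integer_,
                      eventsTarget = NA_integer_, eventsComparator = NA_integer_) {
  hrEst <- !is.null(pooledHr) && pooledHr$estimable
  rdEst <- !is.null(pooledRd) && pooledRd$estimable
  data.frame(
    scope = scope, outcome_id = oid,
    log_hr = if (hrEst) pooledHr$log_hr else NA_real_,
    se_log_hr = if (hrEst) pooledHr$se else NA_real_,
    hr = if (hrEst) exp(pooledHr$log_hr) else NA_real_,
    hr_lo = if (hrEst) pooledHr$ci[1] else NA_real_,
    hr_hi = if (hrEst) pooledHr$ci[2] else NA_real_,
    rd = if (rdEst) pooledRd$rd else NA_real_,
    se_rd = if (rdEst) pooledRd$se else NA_real_,
    rd_lo = if (rdEst) pooledRd$ci[1] else NA_real_,
    rd_hi = if (rdEst) pooledRd$ci[2] else NA_real_,
    n_target = nTarget, n_comparator = nComparator,
    events_target = eventsTarget, events_comparator = eventsComparator,
    suppressed = suppressed, reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Per-stratum audit components of a result set
#' @param results A `resultSet` from [estimateEffects()].
#' @return Data frame of per-stratum Cox and KM components.
#' @export
effectComponents <- function(results) {
  attr(results, "components")
}

#' Per-scope diagnostics of a result set
#' @param results A `resultSet` from [estimateEffects()].
#' @return Named list per scope: propensity fit, overlap %, balance report,
#'   gate status.
#' @export
resultDiagnostics <- function(results) {
  attr(results, "diagnostics")
}

#' @export
print.resultSet <- function(x, ...) {
  cat("Pooled effect estimates (", nrow(x), "cells )\n")
  df <- as.data.frame(x)
  df$hr <- signif(df$hr, 3); df$rd <- signif(df$rd, 3)
  print(df[, c("scope", "outcome_id", "hr", "hr_lo", "hr_hi",
               "rd", "rd_lo", "rd_hi", "suppressed")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
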