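# Diagnostic battery: covariate balance (standardized mean differences
# before/after propensity-score stratification), and negative-control
# empirical calibration of systematic error.

#' Standardized mean difference between arms
#'
#' `smd = (mean_t - mean_c) / sqrt((var_t + var_c) / 2)`.  When the pooled
#' variance is zero the SMD is defined as 0 if the means are equal and an
#' error `degenerate_variance` is raised otherwise.
#'
#' @param xTarget,xComparator Covariate values per arm.
#' @return The standardized mean difference.
#' @export
standardizedMeanDifference <- function(xTarget, xComparator) {
  stopifnot(length(xTarget) > 0, length(xComparator) > 0)
  d <- mean(xTarget) - mean(xComparator)
  pv <- (stats::var(xTarget) + stats::var(xComparator)) / 2
  if (!is.finite(pv) || pv == 0) {
    if (abs(d) < .Machine$double.eps^0.5) return(0)
    rsError("degenerate_variance",
            "zero pooled variance with unequal means")
  }
  d / sqrt(pv)
}

# Stratum-size weighted SMD: within-stratum means and variances per arm,
# combined with weights proportional to total stratum size.
weightedSmd <- function(x, z, stratum) {
  tab <- table(stratum)
  w <- as.numeric(tab) / sum(tab)
  levs <- as.integer(names(tab))
  mT <- mC <- vT <- vC <- ww <- numeric(0)
  for (i in seq_along(levs)) {
    idx <- stratum == levs[i]
    xt <- x[idx & z]; xc <- x[idx & !z]
    if (length(xt) == 0 || length(xc) == 0) next  # stratum missing an arm
    mT <- c(mT, mean(xt)); mC <- c(mC, mean(xc))
    vT <- c(vT, if (length(xt) > 1) stats::var(xt) else 0)
    vC <- c(vC, if (length(xc) > 1) stats::var(xc) else 0)
    ww <- c(ww, w[i])
  }
  if (length(ww) == 0) return(NA_real_)
  ww <- ww / sum(ww)
  d <- sum(ww * mT) - sum(ww * mC)
  pv <- (sum(ww * vT) + sum(ww * vC)) / 2
  if (pv == 0) {
    return(if (abs(d) < .Machine$double.eps^0.5) 0 else Inf)
  }
  d / sqrt(pv)
}

#' Covariate balance before and after propensity-score stratification
#'
#' For every covariate, the SMD between arms in the raw population and the
#' stratum-size-weighted SMD after stratification.  The gate passes when no
#' post-adjustment absolute SMD exceeds the threshold (rule of thumb 0.1).
#'
#' @param pop A `studyPopulation` restricted to the scope of interest.
#' @param strata A `stratumAssignment` for the same subjects.
#' @param threshold Balance gate threshold (default 0.1).
#' @return An object of class `balanceReport`: data frame (`covariate`,
#'   `smd_before`, `smd_after`) plus `max_abs_smd_after`, `gate`,
#'   `threshold`.
#' @export
evaluateBalance <- function(pop, strata, threshold = 0.1) {
  stopifnot(inherits(pop, "studyPopulation"))
  z <- pop$subjects$arm == "target"
  stratum <- strata$stratum[match(pop$subjects$subject_id, strata$subject_id)]
  X <- pop$covariates
  before <- after <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    before[j] <- tryCatch(standardizedMeanDifference(x[z], x[!z]),
                          error = function(e) Inf)
    after[j] <- weightedSmd(x, z, stratum)
  }
  tab <- data.frame(covariate = colnames(X), smd_before = before,
                    smd_after = after, stringsAsFactors = FALSE)
  maxAfter <- max(abs(after), na.rm = TRUE)
  structure(
    list(table = tab, max_abs_smd_after = maxAfter,
         gate = is.finite(maxAfter) && maxAfter <= threshold,
         threshold = threshold),
    class = "balanceReport"
  )
}

#' @export
print.balanceReport <- function(x, ...) {
  cat(sprintf(
    "Balance over %d covariates: max |SMD| after = %.4f (threshold %.2g) -> %s\n",
    nrow(x$table), x$max_abs_smd_after, x$threshold,
    if (x$gate) "PASS" else "FAIL"))
  invisible(x)
}

#' Fit the systematic-error (null) distribution from negative controls
#'
#' Negative-control outcomes have true hazard ratio 1, so their estimates
#' should scatter around 0 on the log scale within sampling error alone.
#' The systematic error is modelled as a Gaussian bias distribution
#' `N(mu, sigma^2)` on the log-HR scale; marginally each control estimate is
#' `N(mu, sigma^2 + se_i^2)`, and `(mu, sigma)` are found by bounded
#' maximum likelihood.
#'
#' @param logHrs Negative-control log hazard-ratio estimates.
#' @param ses Their standard errors.
#' @return An object of class `calibrationModel`: `mu`, `sigma`, `n`,
#'   `logLik`.
#' @export
fitNullDistribution <- function(logHrs, ses) {
  ok <- is.finite(logHrs) & is.finite(ses)
  y <- logHrs[ok]; s <- ses[ok]
  if (length(y) < 2) {
    rsError("insufficient_controls",
            "at least 2 finite control estimates required")
  }
  nll <- function(par) {
    -sum(stats::dnorm(y, par[1], sqrt(par[2]^2 + s^2), log = TRUE))
  }
  start <- c(mean(y), max(stats::sd(y) / 2, 0.01))
  opt <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = c(-10, 0), upper = c(10, 10))
  structure(
    list(mu = opt$par[1], sigma = opt$par[2], n = length(y),
         logLik = -opt$value),
    class = "calibrationModel"
  )
}

#' @export
print.calibrationModel <- function(x, ...) {
  cat(sprintf(
    "Systematic error model: mu = %.4f, sigma = %.4f (from %d controls)\n",
    x$mu, x$sigma, x$n))
  invisible(x)
}

#' Calibrated confidence interval and p-value
#'
#' Shifts an estimate by the fitted systematic-error mean and widens its
#' interval by the systematic-error variance:
#' `(log_hr - mu) +/- 1.96 * sqrt(se^2 + sigma^2)` on the log scale; the
#' calibrated two-sided p-value evaluates the uncorrected estimate against
#' `N(mu, sigma^2 + se^2)`.
#'
#' @param logHr,se Uncalibrated estimate(s) and standard error(s).
#' @param model A `calibrationModel`.
#' @return A data frame: `log_hr`, `se`, `cal_log_hr`, `cal_lo`, `cal_hi`
#'   (log scale), `cal_p`.
#' @export
calibratedInterval <- function(logHr, se, model) {
  stopifnot(inherits(model, "calibrationModel"))
  w <- sqrt(se^2 + model$sigma^2)
  data.frame(
    log_hr = logHr, se = se,
    cal_log_hr = logHr - model$mu,
    cal_lo = (logHr - model$mu) - 1.96 * w,
    cal_hi = (logHr - model$mu) + 1.96 * w,
    cal_p = 2 * stats::pnorm(-abs(logHr - model$mu) / w)
  )
}

#' Coverage of the true null by control confidence intervals
#'
#' Proportion of negative-control 95% confidence intervals containing
#' log hazard ratio 0 (true hazard ratio 1).
#'
#' @param logHrs,ses Control estimates and standard errors; alternatively
#'   pass explicit interval bounds via `lo`/`hi`.
#' @param lo,hi Optional explicit interval bounds on the log scale.
#' @return Fraction of intervals covering the null.
#' @export
controlCoverage <- function(logHrs = NULL, ses = NULL, lo = NULL, hi = NULL) {
  if (is.null(lo) || is.null(hi)) {
    lo <- logHrs - 1.96 * ses
    hi <- logHrs + 1.96 * ses
  }
  mean(lo <= 0 & hi >= 0, na.rm = TRUE)
}
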