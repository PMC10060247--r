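# Propensity machinery: LASSO propensity model, preference-score transform,
# equipoise overlap, and propensity-score quantile stratification.

#' Fit a propensity score model
#'
#' L1-penalized logistic regression of treatment arm on the full candidate
#' covariate set (same machinery as the outcome-risk model).  The propensity
#' score S is the fitted probability of receiving the target treatment; the
#' preference score F rescales S for the treatment prevalence phi so that
#' F = 0.5 indicates clinical equipoise.
#'
#' @param pop A `studyPopulation` (both arms must be present).
#' @param folds CV folds (default 3).
#' @param seed Seed for fold assignment.
#' @param lambda Optional fixed penalty overriding CV selection.
#' @return An object of class `propensityResult`: `scores` data frame
#'   (`subject_id`, `arm`, `score`, `preference`), sparse model
#'   coefficients, the selected lambda and the prevalence `phi`.
#' @export
fitPropensity <- function(pop, folds = 3, seed = 1, lambda = NULL) {
  stopifnot(inherits(pop, "studyPopulation"))
  y <- as.integer(pop$subjects$arm == "target")
  if (length(unique(y)) < 2) {
    rsError("arm_missing", "both treatment arms must be present")
  }
  fit <- fitLassoLogistic(pop$covariates, y, folds = folds, seed = seed,
                          lambda = lambda)
  s <- stats::plogis(sparseLinpred(fit$intercept, fit$coefficients,
                                   pop$covariates))
  phi <- mean(y)
  structure(
    list(
      scores = data.frame(
        subject_id = pop$subjects$subject_id,
        arm = pop$subjects$arm,
        score = s,
        preference = preferenceScore(s, phi),
        stringsAsFactors = FALSE
      ),
      intercept = fit$intercept, coefficients = fit$coefficients,
      lambda = fit$lambda, phi = phi
    ),
    class = "propensityResult"
  )
}

#' @export
print.propensityResult <- function(x, ...) {
  cat(sprintf(
    "Propensity model: %d subjects, phi = %.3f, %d nonzero coefficients (lambda = %.5g)\n",
    nrow(x$scores), x$phi, length(x$coefficients), x$lambda))
  invisible(x)
}

#' Preference score transform
#'
#' Shifts propensity-score logits by the treatment prevalence:
#' `logit(F) = logit(S) - logit(phi)`, so that F = 0.5 marks subjects for
#' whom either treatment is equally likely given their covariates
#' (equipoise), regardless of how common each treatment is overall.
#' Boundary scores are clipped to a machine-safe interval with a diagnostic.
#'
#' @param s Propensity scores in (0, 1).
#' @param phi Target-treatment prevalence in (0, 1).
#' @return Preference scores in (0, 1).
#' @export
preferenceScore <- function(s, phi) {
  stopifnot(phi > 0, phi < 1)
  if (any(s <= 0 | s >= 1)) {
    rsWarning("score_clipped",
              "propensity scores at {0, 1} clipped to a machine-safe interval")
  }
  s <- clipProb(s)
  stats::plogis(stats::qlogis(s) - stats::qlogis(phi))
}

#' Preference-score overlap between arms
#'
#' Overlapping coefficient of the two preference-score distributions,
#' computed on a fixed equal-width partition of `[0, 1]`: the sum over bins
#' of the minimum of the two relative frequencies, as a percentage.  100%
#' means identical distributions; 0% means disjoint support.
#'
#' @param fTarget,fComparator Preference scores of the two arms.
#' @param bins Number of equal-width bins (default 100).
#' @return Overlap percentage in `[0, 100]`.
#' @export
overlapFraction <- function(fTarget, fComparator, bins = 100) {
  stopifnot(length(fTarget) > 0, length(fComparator) > 0)
  breaks <- seq(0, 1, length.out = bins + 1)
  binOf <- function(x) {
    findInterval(pmin(pmax(x, 0), 1), breaks, rightmost.closed = TRUE,
                 all.inside = TRUE)
  }
  ht <- tabulate(binOf(fTarget), nbins = bins) / length(fTarget)
  hc <- tabulate(binOf(fComparator), nbins = bins) / length(fComparator)
  100 * sum(pmin(ht, hc))
}

#' Stratify subjects by propensity-score quantiles
#'
#' Strata are bounded by k-quantiles of the score over the pooled
#' population; a score exactly on a boundary goes to the lower stratum.
#' When the score distribution is too degenerate to support k strata, the
#' effective number of strata is reduced with a diagnostic.
#'
#' @param ps A `propensityResult`.
#' @param k Number of strata (default 5).
#' @return An object of class `stratumAssignment`: a data frame
#'   (`subject_id`, `stratum`) with boundaries as an attribute.
#' @export
stratifyByPs <- function(ps, k = 5) {
  stopifnot(inherits(ps, "propensityResult"))
  s <- ps$scores$score
  if (length(s) < k) rsError("too_few_subjects", "need at least k subjects")
  br <- unname(stats::quantile(s, seq_len(k - 1) / k, type = 7))
  br <- unique(br)
  if (length(br) < k - 1) {
    rsWarning("degenerate_ps",
              "tied propensity-score quantiles; fewer effective strata")
  }
  stratum <- findInterval(s, br, left.open = TRUE) + 1L
  out <- data.frame(subject_id = ps$scores$subject_id, stratum = stratum,
                    stringsAsFactors = FALSE)
  structure(out, boundaries = br, k = length(br) + 1L,
            class = c("stratumAssignment", "data.frame"))
}
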