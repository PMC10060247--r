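# Greedy 1:1 nearest-neighbour propensity matching without replacement,
# with a caliper on the standardized logit scale.

#' Match target to comparator subjects 1:1 on the propensity score
#'
#' Greedy nearest-neighbour matching without replacement.  Target subjects
#' are processed in a seeded random order; each is paired with the nearest
#' unmatched comparator within the caliper.  With
#' `caliperScale = "std_logit"` (the default, matching prevailing
#' comparative-cohort practice) distances are measured on the logit of the
#' score and the caliper equals `caliper` times the pooled SD of the logit
#' scores; `"raw"` uses the score itself.
#'
#' @param ps A `propensityResult`.
#' @param caliper Caliper width (default 0.2).
#' @param caliperScale `"std_logit"` or `"raw"`.
#' @param seed Seed for the target processing order.
#' @return An object of class `matchResult`: `pairs` data frame
#'   (`target_id`, `comparator_id`, `distance`), the absolute caliper used,
#'   and unmatched counts per arm.
#' @export
match1to1 <- function(ps, caliper = 0.2,
                      caliperScale = c("std_logit", "raw"), seed = 1) {
  stopifnot(inherits(ps, "propensityResult"))
  caliperScale <- match.arg(caliperScale)
  sc <- ps$scores
  if (!any(sc$arm == "target") || !any(sc$arm == "comparator")) {
    rsError("arm_missing", "both arms required for matching")
  }
  x <- if (caliperScale == "std_logit") {
    stats::qlogis(clipProb(sc$score))
  } else {
    sc$score
  }
  width <- if (caliperScale == "std_logit") caliper * stats::sd(x) else caliper
  if (!is.finite(width) || width <= 0) width <- Inf

  tIdx <- which(sc$arm == "target")
  cIdx <- which(sc$arm == "comparator")
  ord <- order(x[cIdx])
  cs <- x[cIdx][ord]
  cIds <- sc$subject_id[cIdx][ord]
  nC <- length(cs)

  avail <- rep(TRUE, nC)
  jumpR <- seq_len(nC + 1L)          # next candidate index >= i
  jumpL <- 0L:nC                     # prev candidate index <= i (1-based via i+1)

  nextAvail <- function(i) {
    if (i > nC) return(nC + 1L)
    chain <- integer(0)
    j <- i
    while (j <= nC && !avail[j]) {
      chain <- c(chain, j)
      j <- jumpR[j]
    }
    if (length(chain)) jumpR[chain] <<- j
    j
  }
  prevAvail <- function(i) {
    if (i < 1L) return(0L)
    chain <- integer(0)
    j <- i
    while (j >= 1L && !avail[j]) {
      chain <- c(chain, j)
      j <- jumpL[j + 1L]
    }
    if (length(chain)) jumpL[chain + 1L] <<- j
    j
  }

  tOrder <- withSeed(substreamSeed(seed, "match"), sample(seq_along(tIdx)))
  tgt <- integer(0); cmp <- integer(0); dist <- numeric(0)
  for (ti in tOrder) {
    xt <- x[tIdx[ti]]
    pos <- findInterval(xt, cs)
    r <- nextAvail(pos + 1L)
    l <- prevAvail(pos)
    dr <- if (r <= nC) cs[r] - xt else Inf
    dl <- if (l >= 1L) xt - cs[l] else Inf
    pick <- if (dl <= dr) l else r
    d <- min(dl, dr)
    if (is.finite(d) && d <= width) {
      tgt <- c(tgt, ti); cmp <- c(cmp, pick); dist <- c(dist, d)
      avail[pick] <- FALSE
      jumpR[pick] <- pick + 1L
      jumpL[pick + 1L] <- pick - 1L
    }
  }
  if (length(tgt) == 0) {
    rsError("no_overlap", "no matches within the caliper")
  }
  pairs <- data.frame(
    target_id = sc$subject_id[tIdx][tgt],
    comparator_id = cIds[cmp],
    distance = dist,
    stringsAsFactors = FALSE
  )
  structure(
    list(pairs = pairs, caliper = width, caliper_scale = caliperScale,
         n_unmatched_target = length(tIdx) - nrow(pairs),
         n_unmatched_comparator = length(cIdx) - nrow(pairs)),
    class = "matchResult"
  )
}

#' @export
print.matchResult <- function(x, ...) {
  cat(sprintf(
    "1:1 match: %d pairs (caliper %.4g on %s scale); unmatched target %d, comparator %d\n",
    nrow(x$pairs), x$caliper, x$caliper_scale,
    x$n_unmatched_target, x$n_unmatched_comparator))
  invisible(x)
}

#' Subject ids of the matched subset
#' @param match A `matchResult`.
#' @return Character vector of matched target and comparator ids.
#' @export
matchedSubjects <- function(match) {
  stopifnot(inherits(match, "matchResult"))
  c(match$pairs$target_id, match$pairs$comparator_id)
}
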