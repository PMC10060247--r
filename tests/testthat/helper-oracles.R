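# Independent oracles used to verify the implementation: brute-force
# Breslow partial likelihood, hand product-limit Kaplan-Meier, naive
# all-pairs DeLong placements, grid-search marginal-likelihood MLE.

# Breslow log partial likelihood, computed directly from its definition:
# each event contributes b * z_i - log(sum over the risk set of exp(b * z)).
breslowLogPL <- function(beta, tte, event, z) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- tte >= tte[i]
    ll <- ll + beta * z[i] - log(sum(exp(beta * z[risk])))
  }
  ll
}

bruteForceCoxLogHr <- function(tte, event, z) {
  stats::optimize(function(b) -breslowLogPL(b, tte, event, z),
                  interval = c(-10, 10), tol = 1e-9)$minimum
}

# Hand product-limit estimator with Greenwood variance at a horizon.
handKm <- function(tte, event, horizon) {
  ts <- sort(unique(tte[event == 1 & tte <= horizon]))
  s <- 1
  gw <- 0
  for (t in ts) {
    n <- sum(tte >= t)
    d <- sum(tte == t & event == 1)
    s <- s * (1 - d / n)
    gw <- gw + d / (n * (n - d))
  }
  list(s = s, se = s * sqrt(gw))
}

# Naive all-pairs c-statistic and DeLong variance via explicit placements.
naiveDeLong <- function(risks, labels) {
  pos <- risks[labels == 1]
  neg <- risks[labels == 0]
  m <- length(pos); n <- length(neg)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(pos, function(p) mean(psi(p, neg)), 0)
  v01 <- vapply(neg, function(q) mean(psi(pos, q)), 0)
  auc <- mean(v10)
  se <- sqrt((if (m > 1) var(v10) / m else 0) +
             (if (n > 1) var(v01) / n else 0))
  list(c = auc, se = se)
}

# Grid-search MLE of the Gaussian systematic-error model, maximizing the
# closed-form marginal likelihood over a (mu, sigma) grid.
gridSearchNullMLE <- function(y, s, muGrid, sigmaGrid) {
  best <- c(NA, NA); bestLL <- -Inf
  for (mu in muGrid) {
    for (sg in sigmaGrid) {
      ll <- sum(dnorm(y, mu, sqrt(sg^2 + s^2), log = TRUE))
      if (ll > bestLL) { bestLL <- ll; best <- c(mu, sg) }
    }
  }
  list(mu = best[1], sigma = best[2], logLik = bestLL)
}
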