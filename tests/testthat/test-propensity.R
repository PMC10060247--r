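test_that("preference score matches its closed form and is bijective", {
  expect_equal(preferenceScore(0.3, 0.3), 0.5)   # equipoise point
  expect_equal(preferenceScore(0.42, 0.5), 0.42) # identity at phi = 0.5
  expect_equal(preferenceScore(0.75, 0.25), 0.9) # logit(F) = ln3 + ln3
  s <- seq(0.01, 0.99, by = 0.01)
  f <- preferenceScore(s, 0.2)
  expect_true(all(diff(f) > 0))
  # invert: logit(S) = logit(F) + logit(phi)
  expect_equal(plogis(qlogis(f) + qlogis(0.2)), s, tolerance = 1e-12)
  expect_warning(preferenceScore(c(0, 0.5), 0.3), class = "score_clipped")
})

test_that("overlap fraction matches bin-minima arithmetic", {
  withr::with_seed(2, x <- runif(500))
  expect_equal(overlapFraction(x, x), 100)
  expect_equal(overlapFraction(runif(100, 0, 0.4), runif(100, 0.6, 1)), 0)
  # two-bin histograms 60/40 vs 40/60 -> min(.6,.4) + min(.4,.6) = 80%
  tgt <- c(rep(0.2, 60), rep(0.7, 40))
  cmp <- c(rep(0.2, 40), rep(0.7, 60))
  expect_equal(overlapFraction(tgt, cmp), 80)
  # invariant to arm relabeling
  expect_equal(overlapFraction(tgt, cmp), overlapFraction(cmp, tgt))
})

test_that("unconfounded data give scores near prevalence and equipoise", {
  sc <- simulationScenario(n = 5000, binaryPrevalence = c(0.3, 0.5),
                           nContinuous = 2, treatIntercept = qlogis(0.3),
                           treatCoefs = rep(0, 4), seed = 17)
  study <- simulateCohort(sc)
  pop <- buildStudyPopulation(study$cohorts, study$outcomes,
                              studySpec(outcomeIds = "outcome_1"))
  ps <- fitPropensity(pop, seed = 17)
  expect_lt(sd(ps$scores$score), 0.05)         # S concentrated near phi
  expect_lt(abs(mean(ps$scores$score) - ps$phi), 0.02)
  expect_lt(abs(mean(ps$scores$preference) - 0.5), 0.05)
})

test_that("propensity LASSO with a weak penalty recovers assignment coefficients", {
  beta <- c(0.8, -0.6, 0.5, -0.4, 0.3)
  sc <- simulationScenario(n = 50000, binaryPrevalence = c(0.3, 0.5),
                           nContinuous = 3, treatCoefs = beta, seed = 19)
  study <- simulateCohort(sc)
  pop <- buildStudyPopulation(study$cohorts, study$outcomes,
                              studySpec(outcomeIds = "outcome_1"))
  ps <- fitPropensity(pop, lambda = 1e-6)
  y <- pop$subjects$arm == "target"
  oracle <- coef(glm(y ~ pop$covariates, family = binomial()))[-1]
  got <- ps$coefficients[paste0("x", 1:5)]
  expect_equal(unname(got), unname(oracle), tolerance = 0.01)
  expect_equal(unname(got), beta, tolerance = 0.1)
  # fitted S is monotone in a positive-coefficient covariate
  ord <- order(pop$covariates[, "x3"])
  expect_gt(cor(pop$covariates[, "x3"], ps$scores$score), 0.3)
})

test_that("matching reproduces the greedy oracle on the 3-vs-3 fixture", {
  ps <- structure(list(scores = data.frame(
    subject_id = c("t1", "t2", "t3", "c1", "c2", "c3"),
    arm = rep(c("target", "comparator"), each = 3),
    score = c(0.2, 0.5, 0.8, 0.25, 0.45, 0.9),
    preference = NA
  )), class = "propensityResult")
  m <- match1to1(ps, caliper = 10, caliperScale = "raw", seed = 1)
  pairs <- m$pairs[order(m$pairs$target_id), ]
  # nearest neighbours are unique here, so any processing order pairs
  # t1-c1, t2-c2, t3-c3
  expect_equal(pairs$comparator_id, c("c1", "c2", "c3"))
})

test_that("identical score multisets match the whole smaller arm at distance 0", {
  s <- c(0.2, 0.3, 0.4, 0.6)
  ps <- structure(list(scores = data.frame(
    subject_id = sprintf("p%d", 1:8),
    arm = rep(c("target", "comparator"), each = 4),
    score = c(s, s), preference = NA
  )), class = "propensityResult")
  m <- match1to1(ps, seed = 2)
  expect_equal(nrow(m$pairs), 4)
  expect_equal(m$pairs$distance, rep(0, 4))
  expect_equal(m$n_unmatched_target, 0)
})

test_that("disjoint score ranges beyond the caliper yield no_overlap", {
  ps <- structure(list(scores = data.frame(
    subject_id = sprintf("p%d", 1:6),
    arm = rep(c("target", "comparator"), each = 3),
    score = c(0.9, 0.92, 0.95, 0.05, 0.06, 0.08),
    preference = NA
  )), class = "propensityResult")
  expect_error(match1to1(ps, caliper = 0.01, caliperScale = "raw", seed = 1),
               class = "no_overlap")
})

test_that("matched pairs are disjoint and respect the caliper", {
  sc <- smallScenario(n = 2000, seed = 23)
  study <- simulateCohort(sc)
  pop <- buildStudyPopulation(study$cohorts, study$outcomes,
                              studySpec(outcomeIds = "outcome_1"))
  ps <- fitPropensity(pop, seed = 23)
  m <- match1to1(ps, caliper = 0.2, seed = 23)
  ids <- c(m$pairs$target_id, m$pairs$comparator_id)
  expect_equal(anyDuplicated(ids), 0)
  expect_true(all(m$pairs$distance <= m$caliper))
  arm <- ps$scores$arm[match(m$pairs$target_id, ps$scores$subject_id)]
  expect_true(all(arm == "target"))
})

test_that("PS strata follow pooled quantiles with boundary ties going low", {
  mk <- function(s) structure(list(scores = data.frame(
    subject_id = as.character(seq_along(s)),
    arm = rep(c("target", "comparator"), length.out = length(s)),
    score = s, preference = NA
  )), class = "propensityResult")
  # 10 distinct scores, k = 5 -> consecutive sorted blocks of 2
  s <- seq(0.05, 0.95, by = 0.1)
  st <- stratifyByPs(mk(s), k = 5)
  expect_equal(st$stratum[order(s)], rep(1:5, each = 2))
  # uniform scores -> ~equal stratum sizes
  withr::with_seed(3, u <- runif(5000))
  tab <- table(stratifyByPs(mk(u), k = 5)$stratum)
  expect_equal(unname(tab), rep(1000, 5), ignore_attr = TRUE, tolerance = 0.02)
  # all-identical scores collapse to one stratum with a diagnostic
  expect_warning(st1 <- stratifyByPs(mk(rep(0.4, 10)), k = 5),
                 class = "degenerate_ps")
  expect_equal(unique(st1$stratum), 1L)
  # a score equal to a boundary is assigned to the lower stratum
  s2 <- c(0.1, 0.2, 0.2, 0.4)  # median boundary at 0.2
  st2 <- stratifyByPs(mk(s2), k = 2)
  expect_equal(st2$stratum, c(1L, 1L, 1L, 2L))
})
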