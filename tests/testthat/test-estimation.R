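test_that("stratum Cox log-HR equals brute-force Breslow maximization", {
  # 4-subject fixture: target events at {1, 3}, comparator events at {2, 4}
  tte <- c(1, 3, 2, 4)
  event <- c(1, 1, 1, 1)
  arm <- c("target", "target", "comparator", "comparator")
  fit <- coxStratumHr(tte, event, arm)
  oracle <- bruteForceCoxLogHr(tte, event, as.integer(arm == "target"))
  expect_true(fit$estimable)
  expect_equal(fit$log_hr, oracle, tolerance = 1e-6)
})

test_that("stratum Cox agrees with the brute-force oracle on random small sets", {
  withr::with_seed(41, {
    checked <- 0
    while (checked < 10) {
      n <- sample(5:8, 1)
      tte <- sample(1:12, n, replace = TRUE)  # ties likely
      event <- rbinom(n, 1, 0.7)
      z <- rbinom(n, 1, 0.5)
      arm <- ifelse(z == 1, "target", "comparator")
      fit <- coxStratumHr(tte, event, arm)
      if (!fit$estimable) next
      oracle <- bruteForceCoxLogHr(tte, event, z)
      if (abs(oracle) > 5) next  # near-monotone likelihood, oracle unstable
      expect_equal(fit$log_hr, oracle, tolerance = 1e-6)
      checked <- checked + 1
    }
  })
})

test_that("exchangeable arms give log-HR 0; degenerate strata are flagged", {
  tte <- c(2, 5, 9, 2, 5, 9)
  event <- c(1, 1, 0, 1, 1, 0)
  arm <- rep(c("target", "comparator"), each = 3)
  expect_equal(coxStratumHr(tte, event, arm)$log_hr, 0, tolerance = 1e-6)

  noev <- coxStratumHr(c(1, 2), c(0, 0), c("target", "comparator"))
  expect_false(noev$estimable)
  expect_equal(noev$reason, "no_events")
  single <- coxStratumHr(c(1, 2), c(1, 0), c("target", "target"))
  expect_false(single$estimable)
  expect_equal(single$reason, "single_arm")
})

test_that("randomly permuted arms give a null hazard ratio", {
  withr::with_seed(47, {
    tte <- ceiling(rexp(4000, 1 / 300))
    event <- as.integer(tte <= 730)
    tte <- pmin(tte, 730)
    arm <- sample(rep(c("target", "comparator"), 2000))
  })
  fit <- coxStratumHr(tte, event, arm)
  expect_lt(abs(fit$log_hr), 1.96 * fit$se)
})

test_that("relative pooling follows inverse-variance arithmetic", {
  # homogeneous components (x, s) pool to (x, s / sqrt(k))
  p <- poolRelative(rep(0.3, 4), rep(0.2, 4))
  expect_equal(p$log_hr, 0.3)
  expect_equal(p$se, 0.2 / 2)
  # equal-precision components (0, s), (ln 2, s) -> ln2 / 2
  p2 <- poolRelative(c(0, log(2)), c(0.1, 0.1))
  expect_equal(p2$log_hr, log(2) / 2)
  # a component with near-infinite se carries no weight
  p3 <- poolRelative(c(0.5, 3), c(0.1, 1e8))
  expect_equal(p3$log_hr, 0.5, tolerance = 1e-10)
  # nothing estimable -> suppressed
  expect_false(poolRelative(NA_real_, NA_real_)$estimable)
  # pooled estimate within component range, pooled se <= max component se
  withr::with_seed(6, {
    for (i in 1:5) {
      x <- rnorm(4); s <- runif(4, 0.1, 1)
      p <- poolRelative(x, s)
      expect_gte(p$log_hr, min(x)); expect_lte(p$log_hr, max(x))
      expect_lte(p$se, max(s))
    }
  })
})

test_that("KM risk difference matches hand product-limit computation", {
  # target: 2 subjects, 1 event at t=100 -> S(730) = 0.5
  # comparator: 2 subjects, no events -> S(730) = 1
  tte <- c(100, 730, 730, 730)
  event <- c(1, 0, 0, 0)
  arm <- c("target", "target", "comparator", "comparator")
  rd <- kmStratumRd(tte, event, arm, 730)
  expect_equal(rd$s_target, 0.5)
  expect_equal(rd$s_comparator, 1)
  expect_equal(rd$rd, -0.5)  # higher target incidence favours comparator

  # Greenwood: events at t=1 (n=4) and t=2 (n=3)
  tte2 <- c(1, 2, 5, 5, 9, 9)
  event2 <- c(1, 1, 0, 0, 0, 0)
  arm2 <- c(rep("target", 4), "comparator", "comparator")
  km <- kmStratumRd(tte2[1:4], event2[1:4], rep("target", 4), 9)
  # single-arm stratum is inestimable for a difference
  expect_false(km$estimable)
  both <- kmStratumRd(tte2, event2, arm2, 9)
  hand <- handKm(tte2[1:4], event2[1:4], 9)
  expect_equal(both$s_target, hand$s)
  expect_equal(both$se_target, hand$se)
  expect_equal(both$s_target, 0.5)
  expect_equal(hand$se, 0.5 * sqrt(1 / 12 + 1 / 6))

  # identical arms -> rd exactly 0; no events -> rd 0 with survival 1
  same <- kmStratumRd(c(3, 8, 3, 8), c(1, 0, 1, 0),
                      c("target", "target", "comparator", "comparator"), 10)
  expect_equal(same$rd, 0)
  none <- kmStratumRd(c(5, 5), c(0, 0), c("target", "comparator"), 730)
  expect_equal(none$rd, 0)
  expect_equal(none$s_target, 1)
})

test_that("absolute pooling is a stratum-size weighted mean", {
  p <- poolAbsolute(c(0.01, 0.03), c(0.002, 0.002), c(100, 300))
  expect_equal(p$rd, 0.025)
  # homogeneity and single-stratum pass-through
  expect_equal(poolAbsolute(rep(0.02, 5), rep(0.01, 5), rep(10, 5))$rd, 0.02)
  one <- poolAbsolute(0.04, 0.01, 50)
  expect_equal(one$rd, 0.04)
  expect_equal(one$se, 0.01)
})

test_that("one stratum and no confounding reduces to the crude estimate", {
  sc <- simulationScenario(
    n = 4000, binaryPrevalence = c(0.3, 0.5), nContinuous = 1,
    treatCoefs = rep(0, 3),
    outcomes = list(list(id = "o", logRate = log(2e-04),
                         coefs = c(0.2, 0.2, 0.3), gamma0 = log(0.7),
                         gamma1 = 0)),
    seed = 29)
  study <- simulateCohort(sc)
  pop <- buildStudyPopulation(study$cohorts, study$outcomes,
                              studySpec(outcomeIds = "o"))
  res <- estimateEffects(pop, riskGroups = NULL,
                         config = estimationConfig(kStrata = 1, seed = 29))
  oo <- pop$outcomes$o
  arm <- pop$subjects$arm[match(oo$subject_id, pop$subjects$subject_id)]
  crudeHr <- coxStratumHr(oo$tte, oo$event, arm)
  crudeRd <- kmStratumRd(oo$tte, oo$event, arm, 730)
  expect_equal(res$log_hr[res$scope == "overall"], crudeHr$log_hr,
               tolerance = 1e-10)
  expect_equal(res$rd[res$scope == "overall"], crudeRd$rd, tolerance = 1e-10)
})

test_that("estimateEffects emits a complete grid with audit components", {
  sc <- smallScenario(n = 3000, seed = 31)
  study <- simulateCohort(sc)
  pop <- buildStudyPopulation(study$cohorts, study$outcomes,
                              studySpec(outcomeIds = c("outcome_1", "outcome_2")))
  ps <- fitPropensity(pop, seed = 31)
  m <- match1to1(ps, seed = 31)
  fit <- fitRiskModel(pop, "outcome_1", subjectIds = matchedSubjects(m),
                      seed = 31)
  rg <- assignRiskGroups(predictRisk(fit, pop), quantiles = 3)
  res <- estimateEffects(pop, rg, estimationConfig(seed = 31))
  expect_equal(nrow(res), 2 * (3 + 1))  # outcomes x (groups + overall)
  expect_setequal(unique(res$scope), c("overall", "RG-1", "RG-2", "RG-3"))
  comp <- effectComponents(res)
  expect_true(all(comp$stratum %in% 1:5))
  # pooled cells trace back to their stratum components
  cc <- comp[comp$scope == "overall" & comp$outcome_id == "outcome_1", ]
  p <- poolRelative(cc$log_hr, cc$se_log_hr)
  expect_equal(res$log_hr[res$scope == "overall" &
                          res$outcome_id == "outcome_1"], p$log_hr)
  d <- resultDiagnostics(res)
  expect_setequal(names(d), c("overall", "RG-1", "RG-2", "RG-3"))
  expect_true(all(vapply(d, function(x) is.finite(x$overlap), TRUE)))
})
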