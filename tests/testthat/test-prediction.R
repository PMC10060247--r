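test_that("c-statistic matches closed-form and enumeration fixtures", {
  expect_equal(concordance(c(0.9, 0.1), c(1, 0))$c, 1.0)
  expect_equal(concordance(rep(0.4, 6), c(1, 1, 0, 0, 0, 0))$c, 0.5)
  # all-pairs enumeration: (1 + 0.5 + 1 + 1) / 4
  expect_equal(concordance(c(0.8, 0.6, 0.6, 0.2), c(1, 1, 0, 0))$c, 0.875)
  expect_error(concordance(c(0.2, 0.4), c(1, 1)), class = "undefined_c")
})

test_that("rank-based c-statistic and DeLong SE agree with naive placements", {
  withr::with_seed(31, {
    for (i in 1:12) {
      n <- sample(10:40, 1)
      risks <- round(runif(n), 2)  # rounding forces ties
      labels <- rbinom(n, 1, 0.4)
      if (length(unique(labels)) < 2) next
      fast <- concordance(risks, labels)
      slow <- naiveDeLong(risks, labels)
      expect_equal(fast$c, slow$c, tolerance = 1e-12)
      expect_equal(fast$se, slow$se, tolerance = 1e-12)
    }
  })
})

test_that("c-statistic is invariant to strictly monotone transforms", {
  withr::with_seed(8, {
    risks <- runif(50)
    labels <- rbinom(50, 1, 0.3)
  })
  a <- concordance(risks, labels)$c
  expect_equal(concordance(qlogis(risks), labels)$c, a)
  expect_equal(concordance(risks^3, labels)$c, a)
})

test_that("risk prediction evaluates the sparse logistic closed form", {
  X <- matrix(c(0, 1), ncol = 1, dimnames = list(c("a", "b"), "x1"))
  m <- structure(list(intercept = -4.59512,
                      coefficients = c(x1 = 1.0)),
                 class = "riskModel")
  r <- predictRisk(m, X)
  expect_equal(unname(r["a"]), plogis(-4.59512))
  expect_equal(unname(r["b"]), 0.0267236, tolerance = 1e-5)
  # covariates absent from the data are treated as zero
  X2 <- matrix(0, 1, 1, dimnames = list("c", "other"))
  expect_equal(unname(predictRisk(m, X2)), plogis(-4.59512))
})

test_that("risk is monotone in positive-coefficient covariates", {
  m <- structure(list(intercept = -2, coefficients = c(x1 = 0.8, x2 = -0.5)),
                 class = "riskModel")
  X <- cbind(x1 = seq(0, 3, by = 0.5), x2 = 1)
  expect_true(all(diff(predictRisk(m, X)) > 0))
})

test_that("LASSO keeps a strong signal and zeroes most noise covariates", {
  withr::with_seed(101, {
    n <- 10000
    X <- matrix(rnorm(n * 21), n, 21,
                dimnames = list(NULL, paste0("x", 1:21)))
    y <- rbinom(n, 1, plogis(-2.5 + 2.0 * X[, 1]))
  })
  pop <- popFromLabels(X, y)
  fit <- fitRiskModel(pop, "O1", folds = 3, seed = 1)
  expect_true("x1" %in% names(fit$coefficients))
  noiseKept <- sum(paste0("x", 2:21) %in% names(fit$coefficients))
  expect_lte(noiseKept, 4)  # >= 80% of noise coefficients exactly zero
  # signal direction and rough magnitude against the unpenalized oracle
  oracle <- unname(coef(glm(y ~ X[, 1], family = binomial()))[2])
  expect_gt(fit$coefficients[["x1"]], 0.5 * oracle)
  # refitting with the same seed is deterministic
  fit2 <- fitRiskModel(pop, "O1", folds = 3, seed = 1)
  expect_identical(fit$coefficients, fit2$coefficients)
  expect_identical(fit$lambda, fit2$lambda)
})

test_that("labels independent of covariates give a chance-level CV c-statistic", {
  withr::with_seed(77, {
    X <- matrix(rnorm(4000 * 5), 4000, 5,
                dimnames = list(NULL, paste0("x", 1:5)))
    y <- rbinom(4000, 1, 0.1)
  })
  fit <- fitRiskModel(popFromLabels(X, y), "O1", seed = 3)
  expect_lt(abs(fit$cv_c$c - 0.5), 0.05)
})

test_that("penalty limits: huge lambda -> intercept-only; tiny lambda -> MLE", {
  withr::with_seed(55, {
    X <- matrix(rnorm(3000 * 3), 3000, 3,
                dimnames = list(NULL, paste0("x", 1:3)))
    y <- rbinom(3000, 1, plogis(-1 + 0.8 * X[, 1] - 0.5 * X[, 2]))
  })
  pop <- popFromLabels(X, y)
  hi <- fitRiskModel(pop, "O1", lambda = 1e6)
  expect_length(hi$coefficients, 0)
  lo <- fitRiskModel(pop, "O1", lambda = 1e-6)
  mle <- coef(glm(y ~ X, family = binomial()))
  expect_equal(unname(lo$coefficients[paste0("x", 1:3)]),
               unname(mle[-1]), tolerance = 0.02)
})

test_that("no outcome events in the fitting subset is a structured error", {
  X <- matrix(rnorm(50), 50, 1, dimnames = list(NULL, "x1"))
  expect_error(fitRiskModel(popFromLabels(X, rep(0, 50)), "O1"),
               class = "no_events")
})

test_that("risk groups partition subjects with half-open thresholds", {
  g <- assignRiskGroups(c(a = 0.005, b = 0.012, c = 0.020),
                        thresholds = c(0.01, 0.015))
  expect_equal(as.character(g$group), c("RG-1", "RG-2", "RG-3"))
  # boundary value goes to the upper group
  g2 <- assignRiskGroups(c(x = 0.01), thresholds = c(0.01, 0.015))
  expect_equal(as.character(g2$group), "RG-2")
  expect_error(assignRiskGroups(c(0.1, 0.2), thresholds = c(0.5, 0.5)),
               class = "bad_thresholds")
})

test_that("quantile thresholds yield equal-count groups on continuous risks", {
  withr::with_seed(9, risks <- runif(4000))
  names(risks) <- seq_along(risks)
  g <- assignRiskGroups(risks, quantiles = 4)
  expect_equal(unname(table(g$group)), rep(1000, 4), ignore_attr = TRUE)
  expect_equal(sum(table(g$group)), 4000)
})

test_that("performance table covers the four reporting populations", {
  sc <- smallScenario(n = 2500, seed = 14)
  study <- simulateCohort(sc)
  pop <- buildStudyPopulation(study$cohorts, study$outcomes,
                              studySpec(outcomeIds = c("outcome_1", "outcome_2")))
  ps <- fitPropensity(pop, seed = 14)
  m <- match1to1(ps, seed = 14)
  fit <- fitRiskModel(pop, "outcome_1", subjectIds = matchedSubjects(m),
                      seed = 14)
  perf <- riskModelPerformance(fit, pop, matchedSubjects(m))
  expect_setequal(perf$population,
                  c("matched", "treatment", "comparator", "entire", "matched_cv"))
  expect_true(all(perf$c >= 0 & perf$c <= 1))
  expect_true(all(perf$ci_lo <= perf$c & perf$c <= perf$ci_hi))
})
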