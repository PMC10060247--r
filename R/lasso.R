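# Shared L1-penalized logistic machinery used by both the outcome-risk and
# propensity models: cross-validated lambda on a log grid, seeded stratified
# folds, sparse coefficients reported on the original covariate scale.

stratifiedFolds <- function(y, k, seed) {
  fold <- integer(length(y))
  withSeed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

# Fit LASSO logistic regression with k-fold CV selection of lambda by mean
# cross-validated deviance (no 1-SE rule).  `lambda` overrides CV with a
# fixed penalty.  Returns intercept, nonzero coefficients, the selected
# lambda and prevalidated (out-of-fold) linear predictors.
fitLassoLogistic <- function(x, y, folds = 3, seed = 1,
                             nlambda = 50, lambdaMinRatio = 1e-4,
                             lambda = NULL) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    rsError("degenerate_folds", "response has a single class")
  }
  padded <- FALSE
  if (ncol(x) == 1) {
    # glmnet requires >= 2 columns; a constant column gets coefficient 0
    x <- cbind(x, `.pad.` = 0)
    padded <- TRUE
  }
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(x, y, family = "binomial", lambda = lambda,
                          standardize = TRUE)
    co <- as.matrix(stats::coef(fit, s = lambda))
    preval <- NULL
    sel <- lambda
  } else {
    foldid <- stratifiedFolds(y, folds, substreamSeed(seed, "folds"))
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", foldid = foldid,
                            nlambda = nlambda, lambda.min.ratio = lambdaMinRatio,
                            standardize = TRUE, type.measure = "deviance",
                            keep = TRUE)
    sel <- cv$lambda.min
    co <- as.matrix(stats::coef(cv, s = "lambda.min"))
    idx <- which.min(abs(cv$lambda - sel))
    preval <- cv$fit.preval[, idx]
  }
  intercept <- co[1, 1]
  beta <- co[-1, 1]
  if (padded) beta <- beta[names(beta) != ".pad."]
  beta <- beta[beta != 0]
  list(intercept = intercept, coefficients = beta, lambda = sel,
       preval = preval)
}

# Sparse linear predictor: covariates absent from the model (or from the
# data) contribute 0, matching the absence semantics of sparse features.
sparseLinpred <- function(intercept, beta, X) {
  if (length(beta) == 0) {
    return(rep(intercept, nrow(X)))
  }
  common <- intersect(names(beta), colnames(X))
  lp <- rep(intercept, nrow(X))
  if (length(common)) {
    lp <- lp + as.vector(X[, common, drop = FALSE] %*% beta[common])
  }
  lp
}
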