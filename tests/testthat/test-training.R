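# Standardization, ridge regression, unscaling, metrics, VIF, ranking and
# nested cross-validation.

test_that("standardization fits on the designated rows only and applies everywhere", {
  set.seed(1)
  X <- cbind(a = c(1, 2, 3, 100), b = c(4, 0, -4, 50))
  sc <- standardizeFeatures(X, fitRows = 1:3)
  expect_equal(colMeans(sc$scaled[1:3, ]), c(a = 0, b = 0))
  expect_equal(apply(sc$scaled[1:3, ], 2, sd), c(a = 1, b = 1))
  # the held-out row never influences the parameters (leakage guard): make
  # it arbitrarily extreme and the scaling must not move
  X2 <- X; X2[4, ] <- c(1e6, -1e6)
  sc2 <- standardizeFeatures(X2, fitRows = 1:3)
  expect_identical(sc2$means, sc$means)
  expect_identical(sc2$sds, sc$sds)
  # stored parameters reproduce the scaled matrix
  rebuilt <- sweep(sweep(X, 2, sc$means, "-"), 2, sc$sds, "/")
  expect_equal(rebuilt, sc$scaled)
  expect_error(standardizeFeatures(cbind(k = rep(2, 4)), 1:4),
               "zero-variance.*k")
})

test_that("ridge at alpha 0 equals OLS and large alpha shrinks to the mean", {
  set.seed(2)
  X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  y <- drop(1 + X %*% c(2, -1, 0.5) + rnorm(40, 0, 0.1))
  fit0 <- ridgeFit(X, y, 0)
  ols <- lm(y ~ X)
  expect_equal(unname(fit0$coefficients), unname(coef(ols)[-1]),
               tolerance = 1e-10)
  expect_equal(fit0$intercept, unname(coef(ols)[1]), tolerance = 1e-10)
  fitBig <- ridgeFit(X, y, 1e10)
  expect_lt(max(abs(fitBig$coefficients)), 1e-6)
  expect_equal(fitBig$intercept, mean(y), tolerance = 1e-6)
})

test_that("closed-form ridge matches an iterative solver on random problems", {
  set.seed(3)
  for (i in 1:5) {
    X <- matrix(rnorm(32 * 5), 32, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    y <- rnorm(32)
    alpha <- 10^runif(1, -2, 2)
    fit <- ridgeFit(X, y, alpha)
    ref <- oracleRidge(X, y, alpha)
    expect_equal(unname(fit$coefficients), ref$coefficients, tolerance = 1e-8)
    expect_equal(fit$intercept, ref$intercept, tolerance = 1e-8)
  }
})

test_that("ridge coefficient norm decreases monotonically in alpha", {
  set.seed(4)
  X <- matrix(rnorm(32 * 5), 32, 5)
  colnames(X) <- paste0("f", 1:5)
  y <- rnorm(32)
  norms <- sapply(10^seq(-4, 4, length.out = 15), function(a)
    sqrt(sum(ridgeFit(X, y, a)$coefficients^2)))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("unscaling preserves predictions and recovers generating coefficients", {
  # identity scaling leaves coefficients unchanged
  cf <- c(charge_difference = -2.5, ligand_logp = -0.4, analyte_logp = -0.5,
          ligand_tanimoto = -4.8, analyte_tanimoto = 0.6)
  m <- unscaleModel(cf, 1.2, means = setNames(rep(0, 5), names(cf)),
                    sds = setNames(rep(1, 5), names(cf)))
  expect_equal(modelCoefficients(m), cf)
  expect_equal(modelIntercept(m), 1.2)
  expect_error(unscaleModel(cf, 0, rep(0, 5), rep(0, 5)), "positive")

  # scale -> fit -> unscale: predictions identical in either space
  set.seed(5)
  truth <- publishedModel()
  sim <- generateBindingData(nSystems = 32, noiseSd = 0, seed = 6)
  X <- featureMatrix(sim$dataset)
  y <- dgExperimental(sim$dataset)
  sc <- standardizeFeatures(X)
  fit <- ridgeFit(sc$scaled, y, 1e-8)
  un <- unscaleModel(fit$coefficients, fit$intercept, sc$means, sc$sds)
  predScaled <- drop(sc$scaled %*% fit$coefficients) + fit$intercept
  predRaw <- predict(un, X)
  expect_equal(predRaw, predScaled, tolerance = 1e-10)
  # noiseless identifiability: the generating coefficients come back
  expect_equal(modelCoefficients(un), modelCoefficients(truth),
               tolerance = 1e-3)
  expect_equal(modelIntercept(un), modelIntercept(truth), tolerance = 1e-3)
})

test_that("regression metrics follow their definitions", {
  y <- c(1, 2, 3, 4)
  m <- regressionMetrics(y, y)
  expect_equal(m, list(MSE = 0, MAE = 0, RMSE = 0, R2 = 1))
  m2 <- regressionMetrics(y, rep(mean(y), 4))
  expect_equal(m2$R2, 0)
  # hand-computed case: residuals (-1, 1), SS_res = 2 = SS_tot -> R2 = 0
  m3 <- regressionMetrics(c(0, 2), c(1, 1))
  expect_equal(m3$MAE, 1)
  expect_equal(m3$MSE, 1)
  expect_equal(m3$RMSE, 1)
  expect_equal(m3$R2, 0)
  expect_warning(m4 <- regressionMetrics(c(2, 2), c(1, 3)), "zero-variance")
  expect_true(is.na(m4$R2))
})

test_that("VIF equals the per-feature OLS oracle and detects collinearity", {
  # orthogonal columns -> all VIFs 1
  Xo <- diag(4)[, 1:2]
  Xo <- rbind(Xo, -Xo)
  colnames(Xo) <- c("u", "v")
  expect_equal(unname(vif(Xo)), c(1, 1), tolerance = 1e-12)
  # random matrix vs oracle
  set.seed(8)
  X <- matrix(rnorm(32 * 5), 32, 5, dimnames = list(NULL, paste0("f", 1:5)))
  X[, 2] <- X[, 1] * 0.7 + rnorm(32, 0, 0.5)  # induce some collinearity
  expect_equal(unname(vif(X)), oracleVif(X), tolerance = 1e-8)
  expect_true(all(vif(X) >= 1))
  # duplicated column -> infinite VIF with warning
  Xd <- cbind(X[, 1:2], dup = X[, 1])
  expect_warning(v <- vif(Xd), "collinear")
  expect_true(any(!is.finite(v)))
})

test_that("feature ranking reproduces the published importance order", {
  expect_identical(rankFeatures(publishedModel()),
                   c("charge_difference", "ligand_logp", "analyte_logp",
                     "ligand_tanimoto", "analyte_tanimoto"))
  # ties fall back to canonical order with a warning
  tied <- scoringModel(0, setNames(rep(-1, 5), names(modelCoefficients(publishedModel()))),
                       scaledCoefficients = setNames(c(0.5, -0.5, 0.5, -0.5, 0.5),
                                                     names(modelCoefficients(publishedModel()))))
  expect_warning(rk <- rankFeatures(tied), "tie")
  expect_identical(rk, c("charge_difference", "ligand_logp", "analyte_logp",
                         "ligand_tanimoto", "analyte_tanimoto"))
  noScaled <- scoringModel(0, modelCoefficients(publishedModel()))
  expect_error(rankFeatures(noScaled), "scaled")
})

test_that("nested CV accounts for every system, is seed-deterministic, and respects fold bounds", {
  sim <- generateBindingData(nSystems = 20, noiseSd = 0.45, seed = 9)
  cfg <- cvConfig(nFolds = 5, nRepeats = 4, seed = 21,
                  alphaGrid = 10^seq(-4, 4, length.out = 9))
  cv <- nestedCV(sim$dataset, cfg)
  # every system receives exactly nRepeats out-of-fold predictions
  expect_true(all(is.finite(cvPredictions(cv))))
  expect_identical(dim(cvPredictions(cv)), c(20L, 4L))
  # bit-identical re-run under the same seed
  cv2 <- nestedCV(sim$dataset, cfg)
  expect_identical(cvPredictions(cv2), cvPredictions(cv))
  expect_identical(cv2@chosenAlpha, cv@chosenAlpha)
  # fold bound
  expect_error(nestedCV(sim$dataset, cvConfig(nFolds = 21, nRepeats = 1)),
               "exceeds")
})

test_that("nested CV recovers a noiseless linear signal almost perfectly", {
  sim <- generateBindingData(nSystems = 32, noiseSd = 0, seed = 10)
  cv <- nestedCV(sim$dataset,
                 cvConfig(nFolds = 5, nRepeats = 5, seed = 22,
                          alphaGrid = 10^seq(-6, 2, length.out = 9)))
  expect_gt(cvMetrics(cv)$R2[["mean"]], 0.999)
})

test_that("cluster-wise metrics split by the label column", {
  sim <- generateBindingData(nSystems = 12, noiseSd = 0.2, seed = 13)
  ds <- sim$dataset
  ds@clusterLabel <- rep(c("red", "green"), each = 6)
  cv <- nestedCV(ds, cvConfig(nFolds = 3, nRepeats = 2, seed = 1,
                              alphaGrid = c(0.01, 1)))
  cm <- clusterwiseMetrics(cv, ds)
  expect_identical(sort(cm$cluster), c("green", "red"))
  expect_identical(cm$n, c(6L, 6L))
  expect_error(clusterwiseMetrics(cv, sim$dataset), "no cluster labels")
})
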