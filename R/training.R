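# Training and validation: standardization, closed-form ridge regression,
# nested repeated k-fold cross-validation with alpha grid search, regression
# metrics and variance-inflation-factor diagnostics.

#' Standardize a feature matrix
#'
#' Column-wise standardization (mean 0, unit variance). The scaling
#' parameters are estimated on `fitRows` only and applied to all rows, so
#' that validation rows never leak into the scaling -- the invariant the
#' cross-validation protocol depends on.
#'
#' @param X numeric matrix
#' @param fitRows row indices used to estimate means and sds (default: all)
#' @return list with `scaled` (matrix), `means`, `sds`
#' @export
standardizeFeatures <- function(X, fitRows = seq_len(nrow(X))) {
  stopifnot(is.matrix(X), length(fitRows) >= 1L)
  means <- colMeans(X[fitRows, , drop = FALSE])
  sds <- apply(X[fitRows, , drop = FALSE], 2, stats::sd)
  zero <- sds <= 0 | !is.finite(sds)
  if (any(zero))
    stop("zero-variance feature(s) on fit rows: ",
         paste(colnames(X)[zero], collapse = ", "), call. = FALSE)
  scaled <- sweep(sweep(X, 2, means, "-"), 2, sds, "/")
  list(scaled = scaled, means = means, sds = sds)
}

#' Ridge regression (closed form)
#'
#' L2-penalized least squares with an unpenalized intercept: minimizes
#' ||y - b0 - X b||^2 + alpha ||b||^2. Solved in closed form on centered
#' data: b = (X'X + alpha I)^{-1} X'y. At alpha = 0 with a singular design
#' the pseudo-inverse (minimum-norm) solution is returned with a warning.
#'
#' @param X numeric matrix (typically standardized features)
#' @param y numeric response
#' @param alpha ridge penalty, >= 0
#' @return list with `coefficients` (named as X's columns) and `intercept`
#' @export
ridgeFit <- function(X, y, alpha) {
  stopifnot(is.matrix(X), nrow(X) == length(y), nrow(X) >= 2L,
            length(alpha) == 1L, alpha >= 0)
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm, "-")
  A <- crossprod(Xc) + diag(alpha, ncol(X))
  b <- tryCatch(solve(A, crossprod(Xc, y - ym)),
                error = function(e) {
                  warning("singular ridge system; using pseudo-inverse",
                          call. = FALSE)
                  s <- svd(A)
                  pos <- s$d > max(s$d) * 1e-12
                  s$v[, pos, drop = FALSE] %*%
                    ((t(s$u[, pos, drop = FALSE]) %*%
                        crossprod(Xc, y - ym)) / s$d[pos])
                })
  b <- drop(b)
  names(b) <- colnames(X)
  list(coefficients = b, intercept = ym - sum(xm * b))
}

#' Map a standardized-space fit back to raw feature units
#'
#' Given coefficients fitted on standardized features, returns the
#' equivalent [ScoringModel-class] in raw units: unscaled_i = scaled_i /
#' sd_i, with the intercept shifted by -sum(scaled_i * mean_i / sd_i).
#' Predictions are identical in either space.
#'
#' @param scaledCoefficients named numeric of length 5 (standardized space)
#' @param intercept intercept in standardized space
#' @param means,sds the scaling parameters used for standardization
#' @param provenance free-text provenance for the resulting model
#' @return a [ScoringModel-class] object with scaling metadata attached
#' @export
unscaleModel <- function(scaledCoefficients, intercept, means, sds,
                         provenance = "") {
  if (any(sds <= 0)) stop("sds must be positive", call. = FALSE)
  unscaled <- scaledCoefficients / sds
  scoringModel(intercept = intercept - sum(scaledCoefficients * means / sds),
               coefficients = unscaled,
               scaledCoefficients = scaledCoefficients,
               scaling = list(means = means, sds = sds),
               provenance = provenance)
}

#' Regression performance metrics
#'
#' MSE, MAE, RMSE (= sqrt(MSE)) and R2 (= 1 - SS_res/SS_tot). R2 is NA with
#' a warning when the observed values have zero variance.
#'
#' @param yTrue,yPred equal-length numeric vectors
#' @return named list with `MSE`, `MAE`, `RMSE`, `R2`
#' @export
regressionMetrics <- function(yTrue, yPred) {
  stopifnot(length(yTrue) == length(yPred), length(yTrue) >= 1L)
  res <- yTrue - yPred
  mse <- mean(res^2)
  sstot <- sum((yTrue - mean(yTrue))^2)
  r2 <- if (sstot == 0) {
    warning("R2 undefined: zero-variance observations", call. = FALSE)
    NA_real_
  } else 1 - sum(res^2) / sstot
  list(MSE = mse, MAE = mean(abs(res)), RMSE = sqrt(mse), R2 = r2)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R2_j), with R2_j from regressing feature j on the other
#' features (with intercept); computed as the diagonal of the inverse
#' feature correlation matrix. Always >= 1; perfectly collinear features
#' give Inf with a warning.
#'
#' @param X numeric matrix, n rows > number of columns, no constant column
#' @return named numeric vector of VIFs
#' @export
vif <- function(X) {
  stopifnot(is.matrix(X), nrow(X) > ncol(X))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(X)[sds == 0], collapse = ", "),
         call. = FALSE)
  R <- stats::cor(X)
  if (rcond(R) < 1e-12) {
    warning("perfect collinearity: some VIFs are infinite", call. = FALSE)
    out <- vapply(seq_len(ncol(X)), function(j) {
      r2 <- suppressWarnings(
        summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared)
      if (r2 >= 1 - 1e-8) Inf else 1 / (1 - r2)
    }, numeric(1))
  } else {
    out <- diag(solve(R))
  }
  names(out) <- colnames(X)
  out
}

#' Rank features by importance
#'
#' Orders the five descriptors by decreasing absolute scaled (standardized-
#' space) coefficient. Because all VIFs of the published model are < 3, the
#' scaled-coefficient magnitude is a meaningful importance measure. Ties are
#' broken by canonical feature order, with a warning.
#'
#' @param model a [ScoringModel-class] with scaled coefficients
#' @return character vector of feature names, most important first
#' @export
rankFeatures <- function(model) {
  stopifnot(is(model, "ScoringModel"))
  sc <- model@scaledCoefficients
  if (!length(sc))
    stop("model carries no scaled coefficients; rank needs standardized-space values",
         call. = FALSE)
  mag <- abs(sc)
  if (anyDuplicated(mag))
    warning("tied coefficient magnitudes; tie broken by canonical feature order",
            call. = FALSE)
  # order() is stable, so ties keep canonical order
  names(sc)[order(-mag)]
}

#' Cross-validation configuration
#'
#' @param nFolds number of outer (and inner) folds, default 5
#' @param nRepeats number of repeated shuffles, default 1000
#' @param alphaGrid ridge penalty grid; default 25 log-spaced points over
#'   10^-6..10^6
#' @param seed master RNG seed; per-repeat seeds are derived from it
#' @param innerFolds inner-CV fold count; default mirrors `nFolds`, or
#'   `"loo"` for leave-one-out
#' @return list of class `CVConfig`
#' @export
cvConfig <- function(nFolds = 5L, nRepeats = 1000L,
                     alphaGrid = 10^seq(-6, 6, length.out = 25),
                     seed = 1L, innerFolds = nFolds) {
  stopifnot(nFolds >= 2L, nRepeats >= 1L, all(alphaGrid > 0),
            !is.unsorted(alphaGrid))
  structure(list(nFolds = as.integer(nFolds), nRepeats = as.integer(nRepeats),
                 alphaGrid = as.numeric(alphaGrid), seed = as.integer(seed),
                 innerFolds = innerFolds),
            class = "CVConfig")
}

# Inner CV on the training rows only: mean validation MSE per alpha; returns
# the smallest alpha attaining the minimum (least shrinkage among equals).
.innerSelectAlpha <- function(X, y, alphaGrid, innerFolds) {
  n <- nrow(X)
  k <- if (identical(innerFolds, "loo")) n else min(innerFolds, n)
  folds <- split(seq_len(n), rep_len(seq_len(k), n))
  err <- matrix(NA_real_, length(alphaGrid), k)
  for (j in seq_len(k)) {
    hold <- folds[[j]]
    # tiny inner splits can leave a feature constant; such folds carry no
    # information about alpha and are skipped
    sc <- tryCatch(standardizeFeatures(X, fitRows = setdiff(seq_len(n), hold)),
                   error = function(e) NULL)
    if (is.null(sc)) next
    Xtr <- sc$scaled[-hold, , drop = FALSE]
    ytr <- y[-hold]
    Xho <- sc$scaled[hold, , drop = FALSE]
    for (a in seq_along(alphaGrid)) {
      fit <- ridgeFit(Xtr, ytr, alphaGrid[a])
      pred <- drop(Xho %*% fit$coefficients) + fit$intercept
      err[a, j] <- mean((y[hold] - pred)^2)
    }
  }
  if (all(is.na(err)))
    stop("inner cross-validation failed on every fold (degenerate features)",
         call. = FALSE)
  m <- rowMeans(err, na.rm = TRUE)
  # grid is sorted ascending, so the first minimum is the smallest alpha
  alphaGrid[which.min(m)]
}

#' Nested repeated k-fold cross-validation
#'
#' For each repeat, the systems are shuffled by a seeded RNG and split into
#' `nFolds` outer folds. Per outer fold, the ridge penalty alpha is chosen
#' by an inner cross-validation on the training folds only (grid search,
#' smallest alpha among ties), feature scaling is fit on the training folds
#' only, and out-of-fold predictions are collected. Metrics (MSE, MAE, RMSE,
#' R2) are computed per repeat on out-of-fold predictions only and
#' aggregated across repeats with 2.5/97.5 percentile confidence intervals.
#'
#' @param dataset a [BindingDataset-class] object
#' @param config a [cvConfig()] list
#' @return a [CVResult-class] object
#' @export
nestedCV <- function(dataset, config = cvConfig()) {
  stopifnot(is(dataset, "BindingDataset"), inherits(config, "CVConfig"))
  X <- dataset@features
  y <- dataset@dgExp
  n <- nrow(X)
  if (config$nFolds > n)
    stop("nFolds (", config$nFolds, ") exceeds the number of systems (", n,
         ")", call. = FALSE)
  preds <- matrix(NA_real_, n, config$nRepeats,
                  dimnames = list(dataset@systemId, NULL))
  alphas <- matrix(NA_real_, config$nFolds, config$nRepeats)
  # one master seed spawns per-repeat seeds deterministically
  set.seed(config$seed)
  repSeeds <- sample.int(.Machine$integer.max - 1L, config$nRepeats)
  for (r in seq_len(config$nRepeats)) {
    set.seed(repSeeds[r])
    perm <- sample.int(n)
    folds <- split(perm, rep_len(seq_len(config$nFolds), n))
    for (f in seq_along(folds)) {
      hold <- folds[[f]]
      train <- setdiff(seq_len(n), hold)
      a <- .innerSelectAlpha(X[train, , drop = FALSE], y[train],
                             config$alphaGrid, config$innerFolds)
      alphas[f, r] <- a
      sc <- standardizeFeatures(X, fitRows = train)
      fit <- ridgeFit(sc$scaled[train, , drop = FALSE], y[train], a)
      preds[hold, r] <- drop(sc$scaled[hold, , drop = FALSE] %*%
                               fit$coefficients) + fit$intercept
    }
  }
  perRep <- do.call(rbind, lapply(seq_len(config$nRepeats), function(r) {
    as.data.frame(regressionMetrics(y, preds[, r]))
  }))
  ci <- lapply(perRep, function(v)
    c(mean = mean(v), lo = unname(stats::quantile(v, 0.025)),
      hi = unname(stats::quantile(v, 0.975))))
  new("CVResult", predictions = preds, chosenAlpha = alphas,
      perRepeatMetrics = perRep, summary = ci,
      meanPrediction = rowMeans(preds), config = unclass(config))
}

#' @describeIn nestedCV display a cross-validation result
#' @param object a `CVResult`
#' @export
setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %d systems, %d-fold x %d repeats\n",
              nrow(object@predictions), object@config$nFolds,
              object@config$nRepeats))
  for (m in names(object@summary)) {
    s <- object@summary[[m]]
    cat(sprintf("  %-5s %8.4f  [%.4f, %.4f]\n", m, s[["mean"]], s[["lo"]],
                s[["hi"]]))
  }
})

#' @rdname CVResult-class
#' @param object a `CVResult`
#' @export
setGeneric("cvMetrics", function(object) standardGeneric("cvMetrics"))
#' @rdname CVResult-class
#' @export
setMethod("cvMetrics", "CVResult", function(object) object@summary)

#' @rdname CVResult-class
#' @export
setGeneric("cvPredictions", function(object) standardGeneric("cvPredictions"))
#' @rdname CVResult-class
#' @export
setMethod("cvPredictions", "CVResult", function(object) object@predictions)

#' @rdname CVResult-class
#' @export
setGeneric("meanPrediction", function(object) standardGeneric("meanPrediction"))
#' @rdname CVResult-class
#' @export
setMethod("meanPrediction", "CVResult", function(object) object@meanPrediction)

#' Per-cluster metric breakdown
#'
#' Computes out-of-fold metrics per cluster label (mean prediction across
#' repeats vs experiment), for datasets carrying a `cluster_label` column.
#'
#' @param result a [CVResult-class]
#' @param dataset the [BindingDataset-class] the result was computed from
#' @return data.frame with one row per cluster
#' @export
clusterwiseMetrics <- function(result, dataset) {
  stopifnot(is(result, "CVResult"), is(dataset, "BindingDataset"))
  if (!length(dataset@clusterLabel))
    stop("dataset has no cluster labels", call. = FALSE)
  do.call(rbind, lapply(split(seq_along(dataset@dgExp), dataset@clusterLabel),
    function(ix) {
      m <- regressionMetrics(dataset@dgExp[ix], result@meanPrediction[ix])
      data.frame(cluster = dataset@clusterLabel[ix[1]], n = length(ix),
                 MAE = m$MAE, R2 = m$R2)
    }))
}

#' Final full-data fit
#'
#' Fits the ridge model on the complete dataset at the alpha most often
#' selected in cross-validation (or a user alpha), standardizing on all
#' rows, and returns the model in raw feature units. This mirrors the
#' common practice of exporting a final fit on all data after CV-based
#' validation.
#'
#' @param dataset a [BindingDataset-class]
#' @param alpha ridge penalty; default 1
#' @return a [ScoringModel-class]
#' @export
finalFit <- function(dataset, alpha = 1) {
  stopifnot(is(dataset, "BindingDataset"))
  sc <- standardizeFeatures(dataset@features)
  fit <- ridgeFit(sc$scaled, dataset@dgExp, alpha)
  unscaleModel(fit$coefficients, fit$intercept, sc$means, sc$sds,
               provenance = sprintf(
                 "final full-data ridge fit (alpha=%g, n=%d); fingerprint dialect: %s",
                 alpha, length(dataset@dgExp), .FP_DIALECT))
}
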