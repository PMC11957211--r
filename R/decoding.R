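## Per-time-bin phenotype decoding: cross-validated (multinomial) logistic
## regression on PC features, auROC scoring, shuffled-label nulls, and the
## causal Gaussian AUC smoother.

## Small fixed L2 stabilizer for the logistic fits (the classifier is a
## near-unpenalized GLM; the ridge term only guards against separable bins).
GLM_RIDGE_LAMBDA <- 1e-3

## Stratified fold assignment, seeded: within each class, indices are
## shuffled and folds dealt round-robin.
stratifiedFolds <- function(labels, nFolds, seed) {
  fold <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  fold
}

## Fit the ridge-stabilized logistic model on (x, y) and return held-out
## decision scores: a vector for 2 classes, a samples x classes probability
## matrix otherwise.
glmScores <- function(xTrain, yTrain, xTest) {
  pad <- ncol(xTrain) < 2L   # glmnet needs >= 2 predictors
  if (pad) {
    xTrain <- cbind(xTrain, 0)
    xTest <- cbind(xTest, 0)
  }
  family <- if (nlevels(yTrain) == 2L) "binomial" else "multinomial"
  ## a short decreasing lambda path gives glmnet warm starts, so the fit at
  ## the small target penalty converges even on separable bins
  fit <- glmnet::glmnet(xTrain, yTrain, family = family, alpha = 0,
                        lambda = c(10, 1, 0.1, 0.01, GLM_RIDGE_LAMBDA),
                        standardize = FALSE)
  if (family == "binomial") {
    as.numeric(predict(fit, newx = xTest, type = "link",
                       s = GLM_RIDGE_LAMBDA))
  } else {
    p <- predict(fit, newx = xTest, type = "response", s = GLM_RIDGE_LAMBDA)
    p[, , 1]
  }
}

## auROC of held-out scores: plain AUC for 2 classes, macro-averaged
## one-vs-rest for more.
foldAuc <- function(yTest, scores, classes) {
  if (length(unique(yTest)) < 2L) return(NA_real_)
  if (length(classes) == 2L) {
    rocAuc(yTest == classes[2], scores)
  } else {
    aucs <- vapply(intersect(classes, unique(as.character(yTest))),
                   function(cl) {
      ind <- yTest == cl
      if (all(ind) || !any(ind)) return(NA_real_)
      rocAuc(ind, scores[, cl])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }
}

coerceFeatures <- function(features) {
  if (is.matrix(features)) features <- array(features, c(dim(features), 1L))
  if (length(dim(features)) != 3L)
    stopf("features must be a samples x PCs x bins array (or a matrix)")
  features
}

#' Cross-validated per-bin phenotype decoding
#'
#' For every time bin, a logistic classifier (binomial for two classes,
#' multinomial otherwise, with a small fixed L2 stabilizer) is trained on
#' the first `nPcs` PC coordinates of the training samples and scored on
#' the held-out fold by the area under the ROC curve (macro-averaged
#' one-vs-rest for more than two classes). Folds are stratified by class
#' and seeded; samples are per-trial PC coordinates.
#'
#' @param features samples x PCs x bins numeric array (a samples x PCs
#'   matrix is treated as one bin), e.g. from [neuralTrialFeatures()] or
#'   [facialTrialFeatures()].
#' @param labels Class label per sample (2 or more classes).
#' @param nPcs Leading components used as features (default 8).
#' @param nFolds Cross-validation folds (default 10); reduced with a
#'   warning when the smallest class has fewer samples.
#' @param seed Integer seed for the fold assignment.
#' @param comparison Label stored on the result.
#' @param binTimes Optional bin-center times (s).
#' @return A [DecodingResult-class] with the bins x folds AUC matrix.
#' @rdname decodeTimecourse
#' @export
decodeTimecourse <- function(features, labels, nPcs = 8L, nFolds = 10L,
                             seed = 1L, comparison = NULL, binTimes = NULL) {
  features <- coerceFeatures(features)
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L)
    stopf("decoding needs at least 2 classes")
  if (dim(features)[1] != length(labels))
    stopf("one label per sample is required")
  minClass <- min(table(labels))
  if (minClass < nFolds) {
    warning(sprintf("reducing folds from %d to %d (smallest class size)",
                    nFolds, minClass), call. = FALSE)
    nFolds <- max(2L, as.integer(minClass))
  }
  nPcs <- min(as.integer(nPcs), dim(features)[2])
  nb <- dim(features)[3]
  fold <- stratifiedFolds(labels, nFolds, seed)
  classes <- levels(labels)
  auc <- matrix(NA_real_, nb, nFolds)
  for (b in seq_len(nb)) {
    X <- features[, seq_len(nPcs), b, drop = FALSE][, , 1, drop = FALSE]
    dim(X) <- dim(X)[1:2]
    for (f in seq_len(nFolds)) {
      tr <- fold != f
      scores <- glmScores(X[tr, , drop = FALSE], labels[tr],
                          X[!tr, , drop = FALSE])
      auc[b, f] <- foldAuc(labels[!tr], scores, classes)
    }
  }
  if (is.null(comparison))
    comparison <- paste(classes, collapse = "-vs-")
  if (is.null(binTimes)) binTimes <- seq_len(nb)
  new("DecodingResult", comparison = comparison, aucPerBin = auc,
      shuffleAucPerBin = matrix(numeric(), nb, 0), nPcsUsed = nPcs,
      nFolds = as.integer(nFolds), binTimes = as.numeric(binTimes),
      smoothed = FALSE)
}

#' Shuffled-label null distribution
#'
#' Repeats the cross-validated decoding after globally permuting the class
#' labels (one permutation per column, before the CV split), giving the
#' chance-level AUC distribution against which real decoding performance is
#' compared. Permutations are seeded independently of the fold assignment.
#'
#' @inheritParams decodeTimecourse
#' @param nPerm Number of label permutations (default 100).
#' @return bins x permutations matrix of fold-mean AUC values.
#' @rdname shuffleNull
#' @export
shuffleNull <- function(features, labels, nPerm = 100L, nPcs = 8L,
                        nFolds = 10L, seed = 1L) {
  features <- coerceFeatures(features)
  labels <- droplevels(factor(labels))
  foldSeed <- deriveSeed(seed, "folds")
  nb <- dim(features)[3]
  null <- matrix(NA_real_, nb, nPerm)
  for (p in seq_len(nPerm)) {
    perm <- withr::with_seed(deriveSeed(seed, "perm", p),
                             sample(seq_along(labels)))
    res <- suppressWarnings(
      decodeTimecourse(features, labels[perm], nPcs = nPcs, nFolds = nFolds,
                       seed = foldSeed, comparison = "shuffle"))
    null[, p] <- rowMeans(aucPerBin(res), na.rm = TRUE)
  }
  null
}

#' Empirical permutation p-value for a decoding result
#'
#' `p = (1 + #\{null >= observed\}) / (1 + nPerm)`, comparing the bin-mean
#' observed AUC with the bin-mean of each shuffled-label permutation.
#'
#' @param result A [decodeTimecourse()] result.
#' @param null A [shuffleNull()] matrix for the same features.
#' @return Empirical p-value.
#' @export
decodingPValue <- function(result, null) {
  obs <- mean(meanAuc(result), na.rm = TRUE)
  permMeans <- colMeans(null, na.rm = TRUE)
  (1 + sum(permMeans >= obs)) / (1 + length(permMeans))
}

#' Causal Gaussian smoothing of an AUC time series
#'
#' Gaussian-weighted moving average over the current and previous bins
#' within a trailing window (default 20 s, sigma = window / 3), with the
#' weights renormalized where the window is truncated at the start of the
#' series. Strictly causal: bin t depends only on bins <= t.
#'
#' @param series Numeric AUC per bin.
#' @param binRate Bins per second of the series.
#' @param windowS Trailing window length (s).
#' @param sigma Gaussian sd (s); default `windowS / 3`.
#' @return Smoothed series of the same length.
#' @export
smoothAuc <- function(series, binRate, windowS = 20, sigma = windowS / 3) {
  if (!length(series)) stopf("empty series")
  if (windowS <= 0) stopf("windowS must be > 0")
  lagMax <- floor(windowS * binRate)
  w <- exp(-((0:lagMax) / binRate)^2 / (2 * sigma^2))
  out <- numeric(length(series))
  for (t in seq_along(series)) {
    lags <- 0:min(lagMax, t - 1L)
    out[t] <- sum(w[lags + 1L] * series[t - lags]) / sum(w[lags + 1L])
  }
  out
}
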