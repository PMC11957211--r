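## Internal helpers shared across modules.

#' @importFrom withr with_seed
NULL

## Deterministically derive a child seed (< 2^31) from a master seed and a
## character path such as c("m3", "stress_w6", "neural"). Plain polynomial
## string hash; stable across platforms.
deriveSeed <- function(seed, ...) {
  path <- paste(c(seed, ...), collapse = "/")
  h <- 0
  m <- 2147483647
  for (code in utf8ToInt(path)) h <- (h * 31 + code) %% m
  as.integer(h)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## Euclidean norm of the rows of a matrix.
rowNorms <- function(m) sqrt(rowSums(m * m))

## Interior angle (degrees, in [0, 180]) at vertex b of the triple a-b-c,
## given 2-column coordinate matrices or length-2 vectors.
interiorAngle <- function(a, b, c) {
  a <- rbind(a); b <- rbind(b); c <- rbind(c)
  u <- a - b
  v <- c - b
  cosang <- rowSums(u * v) / (rowNorms(u) * rowNorms(v))
  cosang <- pmin(1, pmax(-1, cosang))
  acos(cosang) * 180 / pi
}

## Shoelace polygon area from x/y coordinate vectors (absolute value).
shoelaceArea <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

## Area under the ROC curve via pROC; `labels` is a 0/1 (or logical) vector,
## `scores` the decision values for the positive class.
rocAuc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stopf("AUC undefined: held-out set contains a single class")
  as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = as.numeric(scores),
    levels = c(0L, 1L), direction = "<", quiet = TRUE)))
}
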