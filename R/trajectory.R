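## State-space core: z-scoring conventions, pooled PCA, trajectory
## construction, and the length / distance metrics shared by the neural and
## facial analyses.

SD_FLOOR <- 1e-9

## Bins of an EventAlignedTensor wholly inside a time window (half-open
## bins [t, t + binWidth)).
binsInWindow <- function(x, window) {
  starts <- x@window[1] + (seq_len(
    if (is(x, "Trajectory")) nrow(x@points) else dim(x@data)[2]) - 1L) *
    x@binWidth
  which(starts >= window[1] - 1e-9 & starts + x@binWidth <= window[2] + 1e-9)
}

#' Local (per-trial baseline) z-score
#'
#' Normalizes every unit on every trial to that trial's own pre-event
#' baseline: `(x - mean(baseline)) / sd(baseline)`, with the baseline taken
#' over the bins inside `baselineWindow`. Baseline standard deviations of
#' zero are floored at 1e-9 and flagged in the returned tensor's
#' `flooredSd` matrix.
#'
#' @param tensor A raw [eventAlignedTensor()].
#' @param baselineWindow `(start, end)` baseline window (s relative to the
#'   event); must lie inside the tensor window and contain at least 2 bins.
#' @return A z-scored `EventAlignedTensor` (`zMode = "local"`).
#' @export
localZscore <- function(tensor, baselineWindow = c(-10, 0)) {
  stopifnot(is(tensor, "EventAlignedTensor"))
  if (baselineWindow[1] < tensor@window[1] - 1e-9 ||
      baselineWindow[2] > tensor@window[2] + 1e-9)
    stopf("baseline window must lie inside the tensor window")
  bb <- binsInWindow(tensor, baselineWindow)
  if (length(bb) < 2L) stopf("baseline must contain at least 2 bins")
  d <- tensor@data
  nu <- dim(d)[1]; nt <- dim(d)[3]
  floored <- matrix(FALSE, nu, nt)
  for (tr in seq_len(nt)) {
    base <- d[, bb, tr, drop = FALSE]
    mu <- rowMeans(base)
    sdv <- apply(base, 1, stats::sd)
    low <- sdv < SD_FLOOR
    floored[low, tr] <- TRUE
    sdv[low] <- SD_FLOOR
    d[, , tr] <- (d[, , tr] - mu) / sdv
  }
  eventAlignedTensor(d, binWidth = tensor@binWidth, window = tensor@window,
                     event = tensor@event, zMode = "local",
                     flooredSd = floored, nDropped = tensor@nDropped)
}

#' Super-global z-score across sessions
#'
#' Z-scores each neuron's full activity trace using the mean and sd pooled
#' over the concatenated frames of all supplied sessions, so that responses
#' recorded in different sessions of the same tracked cells live on one
#' common scale. The sessions must carry the same neurons in the same row
#' order (e.g. ROI-matched activity matrices).
#'
#' @param sessions List of [neuralSession()] objects with aligned rows.
#' @return List of sessions with the activity replaced by its super-global
#'   z-score.
#' @export
superGlobalZscore <- function(sessions) {
  mats <- lapply(sessions, activityMatrix)
  n <- vapply(mats, nrow, integer(1))
  if (length(unique(n)) != 1L)
    stopf("sessions must carry the same (matched) neurons")
  all <- do.call(cbind, mats)
  mu <- rowMeans(all)
  sdv <- apply(all, 1, stats::sd)
  sdv[sdv < SD_FLOOR] <- SD_FLOOR
  lapply(sessions, function(s) {
    z <- (activityMatrix(s) - mu) / sdv
    neuralSession(z, frameRate = frameRate(s), roiIds = roiIds(s),
                  mouseId = mouseId(s), epoch = epochOf(s))
  })
}

#' Fit a PCA model on pooled mean responses
#'
#' Principal component analysis of a units x columns matrix whose columns
#' are mean z-scored responses concatenated across events, groups and weeks
#' (time bins as observations, units as variables). Each unit is centered by
#' its mean over the training columns; no variance scaling is applied (the
#' inputs are already z-scored). The returned loadings are orthonormal and
#' the component variances non-increasing; explained-variance fractions sum
#' to one over all components.
#'
#' @param mat Numeric units x columns matrix, finite, at least 2 x 2.
#' @return A [PCModel-class] object.
#' @rdname fitPCA
#' @export
fitPCA <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stopf("PCA needs at least 2 units and 2 columns")
  if (!all(is.finite(mat))) stopf("PCA input must be finite")
  if (all(apply(mat, 1, stats::sd) < SD_FLOOR))
    stopf("degenerate input: matrix has rank 0 after centering")
  p <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  keep <- p$sdev > 1e-12      # drop numerically null components
  keep[1] <- TRUE
  new("PCModel", loadings = p$rotation[, keep, drop = FALSE],
      variances = p$sdev[keep]^2,
      totalVariance = sum(p$sdev^2),
      center = as.numeric(p$center))
}

#' Project a mean response into PC space
#'
#' Builds a state-space trajectory by multiplying the (centered) mean
#' z-score response by the PCA coefficients:
#' `points = t(response - center) %*% loadings[, 1:nPcs]`.
#' A subset of model units may be projected via `rows` (used by the
#' leave-one-animal-out resampling and per-mouse analyses); the centering
#' and loading rows are subset accordingly.
#'
#' @param model A [fitPCA()] model.
#' @param meanResponse units x bins matrix of mean z-scored responses.
#' @param nPcs Number of leading components to keep.
#' @param binWidth,window Bin grid of the response (defaults 0.1 s over
#'   -10..10 s).
#' @param label Condition label stored on the trajectory.
#' @param rows Optional integer index of model units corresponding to the
#'   rows of `meanResponse`.
#' @return A [Trajectory-class] object.
#' @export
projectTrajectory <- function(model, meanResponse, nPcs,
                              binWidth = 0.1, window = c(-10, 10),
                              label = "trajectory", rows = NULL) {
  stopifnot(is(model, "PCModel"))
  meanResponse <- as.matrix(meanResponse)
  if (nPcs > ncol(model@loadings))
    stopf("nPcs (%d) exceeds the %d fitted components", nPcs,
          ncol(model@loadings))
  if (is.null(rows)) rows <- seq_len(nrow(model@loadings))
  if (nrow(meanResponse) != length(rows))
    stopf("unit dimension (%d) does not match the projected model rows (%d)",
          nrow(meanResponse), length(rows))
  pts <- t(meanResponse - model@center[rows]) %*%
    model@loadings[rows, seq_len(nPcs), drop = FALSE]
  new("Trajectory", points = pts, binWidth = binWidth,
      window = as.numeric(window), label = label)
}

#' Trajectory length
#'
#' Sum of Euclidean distances between adjacent time-bin points, optionally
#' restricted to a sub-window (e.g. the post-event 0--10 s used for the
#' reward/punishment quantification).
#'
#' @param traj A [Trajectory-class].
#' @param window Optional `(start, end)` sub-window (s); default the whole
#'   trajectory.
#' @return Path length in PC-space units.
#' @export
trajectoryLength <- function(traj, window = NULL) {
  stopifnot(is(traj, "Trajectory"))
  idx <- if (is.null(window)) seq_len(nrow(traj@points))
         else binsInWindow(traj, window)
  if (length(idx) < 2L) stopf("need at least 2 bins inside the window")
  steps <- diff(traj@points[idx, , drop = FALSE])
  sum(sqrt(rowSums(steps^2)))
}

#' Bin-by-bin trajectory distance
#'
#' Euclidean distance between two trajectories at every time bin, plus the
#' mean over bins. The trajectories must share the bin grid and the number
#' of components.
#'
#' @param a,b [Trajectory-class] objects on identical grids.
#' @return List with `perBin` (one distance per bin) and `mean`.
#' @export
trajectoryDistance <- function(a, b) {
  stopifnot(is(a, "Trajectory"), is(b, "Trajectory"))
  if (!isTRUE(all.equal(a@binWidth, b@binWidth)) ||
      !isTRUE(all.equal(a@window, b@window)) ||
      !all(dim(a@points) == dim(b@points)))
    stopf("trajectories must share the bin grid and number of PCs")
  d <- sqrt(rowSums((a@points - b@points)^2))
  list(perBin = d, mean = mean(d))
}

#' Components needed to reach a variance fraction
#'
#' Smallest number of leading components whose cumulative explained-variance
#' fraction reaches `fraction`. The stock analyses use 0.60 for neural and
#' 0.90 for facial trajectories.
#'
#' @param model A [PCModel-class].
#' @param fraction Target fraction in (0, 1].
#' @return Integer component count.
#' @export
pcsForVariance <- function(model, fraction) {
  if (fraction <= 0 || fraction > 1) stopf("fraction must lie in (0, 1]")
  cum <- cumsum(varianceFractions(model))
  n <- which(cum >= fraction - 1e-12)[1]
  if (is.na(n)) length(cum) else as.integer(n)
}
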