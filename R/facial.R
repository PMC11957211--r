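## Facial keypoint analysis: track smoothing and calibration, the facial
## expression feature set (pairwise distances, interior angles, kinematics,
## region areas), and baseline-normalized facial trajectory statistics.

#' The 13-point facial skeleton
#'
#' Default skeleton: four eye points (upper/lower/inner/outer), two whisker
#' stems, four nose points (nose_upper, nose_tip, nostril_left,
#' nostril_right), and three mouth-area points (mouth_upper, mouth_lower,
#' chin). The default feature registry derives all 78 pairwise distances,
#' six named interior angles (eye corners, nostril flare, nose bridge,
#' mouth opening, whisker spread), nose-tip and eye-centroid kinematics,
#' and the eye / nose / mouth region areas.
#'
#' @return A `FacialSkeleton` object.
#' @export
facialSkeleton <- function() {
  nodes <- c("upper_eye", "lower_eye", "inner_eye", "outer_eye",
             "top_whisker_stem", "bottom_whisker_stem",
             "nose_upper", "nose_tip", "nostril_left", "nostril_right",
             "mouth_upper", "mouth_lower", "chin")
  new("FacialSkeleton", nodes = nodes,
      regions = list(
        eye = c("upper_eye", "inner_eye", "lower_eye", "outer_eye"),
        nose = c("nose_upper", "nostril_left", "nose_tip", "nostril_right"),
        mouth = c("mouth_upper", "mouth_lower", "chin")),
      angleTriples = list(
        eye_inner_corner = c("upper_eye", "inner_eye", "lower_eye"),
        eye_outer_corner = c("upper_eye", "outer_eye", "lower_eye"),
        nostril_flare = c("nostril_left", "nose_tip", "nostril_right"),
        nose_bridge = c("nose_upper", "nose_tip", "chin"),
        mouth_opening = c("mouth_upper", "mouth_lower", "chin"),
        whisker_spread = c("top_whisker_stem", "nose_upper",
                           "bottom_whisker_stem")),
      kinematicNodes = list(
        nose_tip = "nose_tip",
        eye_centroid = c("upper_eye", "lower_eye", "inner_eye", "outer_eye")))
}

## Linear interpolation over low-confidence keypoints, per node and axis.
## Leading/trailing gaps take the nearest observed value.
fillGaps <- function(coords, confThreshold = 0.5) {
  nf <- dim(coords)[1]
  for (n in seq_len(dim(coords)[2])) {
    bad <- coords[, n, 3] < confThreshold
    if (!any(bad) || all(bad)) next
    good <- which(!bad)
    for (ax in 1:2) {
      coords[, n, ax] <- stats::approx(good, coords[good, n, ax],
                                       xout = seq_len(nf), rule = 2)$y
    }
  }
  coords
}

#' Savitzky-Golay smoothing of a keypoint track
#'
#' Low-confidence keypoints (confidence below `confThreshold`) are first
#' linearly interpolated from their neighbors, then every node/axis series
#' is smoothed with a Savitzky-Golay polynomial filter (default order 2
#' over a 5-frame window), which preserves constant and linear motion while
#' attenuating frame-to-frame tracking noise. Edges are handled by the
#' filter's polynomial fit over the truncated one-sided windows.
#'
#' @param track A [keypointTrack()].
#' @param windowFrames Odd window length (frames), default 5.
#' @param polyorder Polynomial order, default 2 (< `windowFrames`).
#' @param confThreshold Gap-fill confidence threshold.
#' @return The smoothed `KeypointTrack`.
#' @export
smoothTrack <- function(track, windowFrames = 5L, polyorder = 2L,
                        confThreshold = 0.5) {
  stopifnot(is(track, "KeypointTrack"))
  nf <- dim(track@coords)[1]
  if (windowFrames %% 2L == 0L) stopf("windowFrames must be odd")
  if (polyorder >= windowFrames)
    stopf("polyorder must be smaller than the window")
  if (windowFrames >= nf)
    stopf("window (%d) must be shorter than the track (%d frames)",
          windowFrames, nf)
  coords <- fillGaps(track@coords, confThreshold)
  for (n in seq_len(dim(coords)[2]))
    for (ax in 1:2)
      coords[, n, ax] <- signal::sgolayfilt(coords[, n, ax], p = polyorder,
                                            n = windowFrames)
  keypointTrack(coords, nodes = track@nodes, fps = track@fps,
                pxPerCm = track@pxPerCm)
}

#' Spout-based pixel-to-cm calibration
#'
#' Sets the track's px-per-cm conversion factor from the measured length of
#' the sucrose spout in the video, removing camera-placement bias from all
#' downstream distance-based features.
#'
#' @param track A [keypointTrack()].
#' @param spoutLengthPx Spout length in the video (px), > 0.
#' @param spoutLengthCm Physical spout length (cm), > 0.
#' @return The track with `pxPerCm = spoutLengthPx / spoutLengthCm`.
#' @export
calibrateTrack <- function(track, spoutLengthPx, spoutLengthCm) {
  stopifnot(is(track, "KeypointTrack"))
  if (spoutLengthPx <= 0 || spoutLengthCm <= 0)
    stopf("spout lengths must be > 0")
  keypointTrack(track@coords, nodes = track@nodes, fps = track@fps,
                pxPerCm = spoutLengthPx / spoutLengthCm)
}

## Speed (units/s) and acceleration magnitude (units/s^2) of a frames x 2
## position series: central differences in the interior, one-sided at the
## edges; acceleration endpoints replicate the nearest interior value.
pointKinematics <- function(pos, fps) {
  nf <- nrow(pos)
  v <- matrix(NA_real_, nf, 2)
  v[1, ] <- (pos[2, ] - pos[1, ]) * fps
  v[nf, ] <- (pos[nf, ] - pos[nf - 1, ]) * fps
  if (nf > 2) {
    i <- 2:(nf - 1)
    v[i, ] <- (pos[i + 1, , drop = FALSE] - pos[i - 1, , drop = FALSE]) / 2 * fps
  }
  a <- matrix(0, nf, 2)
  if (nf > 2) {
    i <- 2:(nf - 1)
    a[i, ] <- (pos[i + 1, , drop = FALSE] - 2 * pos[i, , drop = FALSE] +
                 pos[i - 1, , drop = FALSE]) * fps^2
    a[1, ] <- a[2, ]
    a[nf, ] <- a[nf - 1, ]
  }
  list(speed = sqrt(rowSums(v^2)), accel = sqrt(rowSums(a^2)))
}

#' Extract the facial expression feature set
#'
#' Derives the full feature registry of a skeleton from a calibrated
#' keypoint track: all pairwise inter-keypoint distances (cm), the
#' registry's interior angles (degrees, vertex at the middle node of each
#' triple, in \[0, 180\]), speed and acceleration magnitudes of the
#' registry's kinematic targets (cm/s, cm/s^2; point or node-centroid
#' positions, central differences scaled by the frame rate), and the
#' shoelace areas of the eye / nose / mouth polygons (cm^2). With the
#' default 13-point skeleton this yields 78 + 6 + 4 + 3 = 91 channels.
#'
#' @param track A calibrated (see [calibrateTrack()]) `KeypointTrack`,
#'   typically smoothed first.
#' @param skeleton A [facialSkeleton()]; registry entries must cite existing
#'   nodes.
#' @return A [FacialFeatureMatrix-class]: channels x frames with per-channel
#'   kind/units metadata.
#' @rdname extractFacialFeatures
#' @export
extractFacialFeatures <- function(track, skeleton = facialSkeleton()) {
  stopifnot(is(track, "KeypointTrack"), is(skeleton, "FacialSkeleton"))
  if (is.na(track@pxPerCm))
    stopf("track must be calibrated (see calibrateTrack) before feature extraction")
  if (!all(skeleton@nodes %in% track@nodes))
    stopf("track is missing skeleton node(s): %s",
          paste(setdiff(skeleton@nodes, track@nodes), collapse = ", "))
  sc <- track@pxPerCm
  xy <- function(node) track@coords[, match(node, track@nodes), 1:2,
                                    drop = TRUE]
  centroid <- function(nodes) {
    idx <- match(nodes, track@nodes)
    cbind(rowMeans(track@coords[, idx, 1, drop = FALSE]),
          rowMeans(track@coords[, idx, 2, drop = FALSE]))
  }
  vals <- list(); info <- list()
  addChannel <- function(name, kind, units, v) {
    vals[[length(vals) + 1L]] <<- v
    info[[length(info) + 1L]] <<- data.frame(name = name, kind = kind,
                                             units = units)
  }
  pairs <- utils::combn(skeleton@nodes, 2)
  for (j in seq_len(ncol(pairs))) {
    p <- xy(pairs[1, j]); q <- xy(pairs[2, j])
    addChannel(paste0("dist_", pairs[1, j], "__", pairs[2, j]),
               "distance", "cm",
               sqrt(rowSums((p - q)^2)) / sc)
  }
  for (an in names(skeleton@angleTriples)) {
    tri <- skeleton@angleTriples[[an]]
    addChannel(paste0("angle_", an), "angle", "deg",
               interiorAngle(xy(tri[1]), xy(tri[2]), xy(tri[3])))
  }
  for (kn in names(skeleton@kinematicNodes)) {
    pos <- centroid(skeleton@kinematicNodes[[kn]]) / sc
    kin <- pointKinematics(pos, track@fps)
    addChannel(paste0("speed_", kn), "velocity", "cm/s", kin$speed)
    addChannel(paste0("accel_", kn), "acceleration", "cm/s^2", kin$accel)
  }
  for (rn in names(skeleton@regions)) {
    idx <- match(skeleton@regions[[rn]], track@nodes)
    x <- track@coords[, idx, 1, drop = FALSE] / sc
    y <- track@coords[, idx, 2, drop = FALSE] / sc
    area <- vapply(seq_len(nrow(x)),
                   function(f) shoelaceArea(x[f, , 1], y[f, , 1]),
                   numeric(1))
    addChannel(paste0("area_", rn), "area", "cm^2", area)
  }
  infoDf <- do.call(rbind, info)
  values <- do.call(rbind, vals)
  rownames(values) <- infoDf$name
  new("FacialFeatureMatrix",
      values = values,
      channelInfo = DataFrame(infoDf, row.names = infoDf$name),
      fps = track@fps)
}

## Wrap a feature matrix as a NeuralSession so the event-alignment machinery
## applies unchanged (channels play the role of units).
featureSession <- function(features, subject = "s1") {
  neuralSession(featureValues(features), frameRate = features@fps,
                roiIds = features@channelInfo$name, mouseId = subject,
                epoch = "facial")
}

## Align a feature matrix to CS onsets of one trial type and z-score each
## trial to its immediately preceding baseline window.
facialEventTensor <- function(features, trials, trialType = "reward",
                              window = c(-10, 10), binWidth = 0.1,
                              baselineSeconds = 5) {
  event <- if (startsWith(trialType, "reward")) "reward_CS" else "punish_CS"
  tensor <- alignEvents(featureSession(features), trials, event,
                        window = window, binWidth = binWidth)
  localZscore(tensor, baselineWindow = c(-baselineSeconds, 0))
}

#' Facial trajectory difference score
#'
#' Per-subject facial dynamics score: every trial of the requested type is
#' aligned to CS onset, normalized to its own 5-s pre-trial baseline,
#' trial-averaged, and projected through a PCA fit once on the pooled
#' feature responses of all subjects (the channels are shared, so all
#' subjects use the same loadings). The score is the post-event trajectory
#' length (0..10 s) minus the pre-event length (-10..0 s): positive values
#' mean facial dynamics increase after the cue.
#'
#' @param featuresList Named list (by subject) of [FacialFeatureMatrix-class]
#'   objects, all with identical channel registries.
#' @param trialsList Named list of the matching trial tables.
#' @param trialType `"reward"` or `"punish"`.
#' @param window,binWidth Peri-event grid.
#' @param baselineSeconds Per-trial baseline length (s) immediately before
#'   CS onset.
#' @param varianceFraction PC count rule (default 0.90); overridden by
#'   `nPcs`.
#' @param nPcs Optional fixed component count.
#' @return Data frame with `subject`, `score`, `length_post`, `length_pre`,
#'   `n_dropped` columns; the fitted model and PC count as attributes.
#' @export
facialDifferenceScore <- function(featuresList, trialsList,
                                  trialType = "reward", window = c(-10, 10),
                                  binWidth = 0.1, baselineSeconds = 5,
                                  varianceFraction = 0.9, nPcs = NULL) {
  subjects <- names(featuresList)
  tensors <- lapply(subjects, function(s)
    facialEventTensor(featuresList[[s]], trialsList[[s]], trialType,
                      window, binWidth, baselineSeconds))
  names(tensors) <- subjects
  means <- lapply(tensors, trialMean)
  model <- fitPCA(do.call(cbind, means))   # shared channel space
  if (is.null(nPcs)) nPcs <- pcsForVariance(model, varianceFraction)
  out <- do.call(rbind, lapply(subjects, function(s) {
    traj <- projectTrajectory(model, means[[s]], nPcs, binWidth = binWidth,
                              window = window, label = s)
    post <- trajectoryLength(traj, c(0, window[2]))
    pre <- trajectoryLength(traj, c(window[1], 0))
    data.frame(subject = s, score = post - pre, length_post = post,
               length_pre = pre, n_dropped = tensors[[s]]@nDropped,
               stringsAsFactors = FALSE)
  }))
  attr(out, "nPcs") <- nPcs
  attr(out, "model") <- model
  rownames(out) <- NULL
  out
}

#' Per-trial facial PC features for phenotype decoding
#'
#' Facial analogue of [neuralTrialFeatures()]: trials are aligned and
#' baseline-normalized as in [facialDifferenceScore()], a single PCA is fit
#' on the pooled trial-mean responses, and each individual trial is
#' projected into that space (all subjects share the loadings since the
#' feature channels are common).
#'
#' @inheritParams facialDifferenceScore
#' @param labels Named character/factor: phenotype per subject.
#' @param nPcs Components kept as features (default 8).
#' @return List with `features` (samples x PCs x bins), `labels`, `mouse`,
#'   `model`.
#' @export
facialTrialFeatures <- function(featuresList, trialsList, labels,
                                trialType = "reward", nPcs = 8L,
                                window = c(-10, 10), binWidth = 0.1,
                                baselineSeconds = 5) {
  subjects <- names(featuresList)
  tensors <- lapply(subjects, function(s)
    facialEventTensor(featuresList[[s]], trialsList[[s]], trialType,
                      window, binWidth, baselineSeconds))
  names(tensors) <- subjects
  model <- fitPCA(do.call(cbind, lapply(tensors, trialMean)))
  nPcs <- min(nPcs, ncol(model@loadings))
  W <- model@loadings[, seq_len(nPcs), drop = FALSE]
  nb <- dim(tensors[[1]]@data)[2]
  featList <- list(); labVec <- character(); subjVec <- character()
  for (s in subjects) {
    d <- tensors[[s]]@data
    for (tr in seq_len(dim(d)[3])) {
      featList[[length(featList) + 1L]] <- t(W) %*% (d[, , tr] - model@center)
      labVec <- c(labVec, as.character(labels[[s]]))
      subjVec <- c(subjVec, s)
    }
  }
  features <- array(NA_real_, c(length(featList), nPcs, nb))
  for (i in seq_along(featList)) features[i, , ] <- featList[[i]]
  list(features = features, labels = factor(labVec), mouse = subjVec,
       model = model)
}
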