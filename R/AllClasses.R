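#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
NULL

#' Canonical epoch labels of the chronic-mild-stress timeline
#'
#' Ten weekly imaging/behavior sessions: a pre-stress baseline, six weeks of
#' unpredictable chronic mild stress (the last of which is the "post-stress"
#' time point), a saline injection control week, a ketamine week, and a
#' post-ketamine follow-up.
#'
#' @return Character vector of the ten epoch tags in chronological order.
#' @export
cmsEpochs <- function() {
  c("baseline", paste0("stress_w", 1:6), "saline", "ketamine", "post_ketamine")
}

## The post-stress time point used throughout the analyses is the final
## stress week.
postStressEpoch <- function() "stress_w6"

phenotypeLevels <- function() c("control", "resilient", "susceptible", "neutral")

# ---------------------------------------------------------------------------
# Session design
# ---------------------------------------------------------------------------

#' @rdname SessionDesign
#' @export
setClass("SessionDesign", representation(
  nReward = "integer", nRewardCatch = "integer",
  nPunish = "integer", nPunishCatch = "integer",
  csDuration = "numeric", usDelay = "numeric",
  itiRange = "numeric",
  rewardToneKHz = "numeric", punishToneKHz = "numeric",
  frameRateNeural = "numeric", frameRateVideo = "numeric"
))

setValidity("SessionDesign", function(object) {
  msg <- character()
  if (object@nReward < 3L)
    msg <- c(msg, "nReward must be >= 3 (the first three trials are reward trials)")
  if (any(c(object@nRewardCatch, object@nPunish, object@nPunishCatch) < 0L))
    msg <- c(msg, "trial counts must be non-negative")
  if (object@csDuration <= 0) msg <- c(msg, "csDuration must be > 0")
  if (object@usDelay < 0) msg <- c(msg, "usDelay must be >= 0")
  if (length(object@itiRange) != 2L || object@itiRange[1] > object@itiRange[2])
    msg <- c(msg, "itiRange must be (lo, hi) with lo <= hi")
  if (object@frameRateNeural <= 0 || object@frameRateVideo <= 0)
    msg <- c(msg, "frame rates must be > 0")
  if (length(msg)) msg else TRUE
})

#' Pavlovian discrimination session design
#'
#' Describes the trial composition and timing of one head-fixed acquisition
#' session. The defaults are the acquisition protocol: 36 reward trials
#' (no lick contingency), 2 reward catch trials, 8 punishment trials and
#' 2 punishment catch trials; a 5-s pure-tone CS (9 kHz reward, 2 kHz
#' punishment) with the US delivered 2 s after CS onset on non-catch trials;
#' 25--30 s inter-trial intervals; calcium imaging at ~29.8 Hz and facial
#' video at 30 fps.
#'
#' @param nReward,nRewardCatch,nPunish,nPunishCatch Trial counts per session.
#' @param csDuration CS tone duration (s).
#' @param usDelay Delay from CS onset to US delivery (s).
#' @param itiRange Inter-trial interval range (s), sampled uniformly.
#' @param rewardToneKHz,punishToneKHz CS tone frequencies (kHz).
#' @param frameRateNeural Imaging frame rate (Hz).
#' @param frameRateVideo Facial video frame rate (fps).
#'
#' @return A `SessionDesign` object.
#' @export
sessionDesign <- function(nReward = 36L, nRewardCatch = 2L,
                          nPunish = 8L, nPunishCatch = 2L,
                          csDuration = 5, usDelay = 2,
                          itiRange = c(25, 30),
                          rewardToneKHz = 9, punishToneKHz = 2,
                          frameRateNeural = 29.8, frameRateVideo = 30) {
  new("SessionDesign",
      nReward = as.integer(nReward), nRewardCatch = as.integer(nRewardCatch),
      nPunish = as.integer(nPunish), nPunishCatch = as.integer(nPunishCatch),
      csDuration = csDuration, usDelay = usDelay, itiRange = as.numeric(itiRange),
      rewardToneKHz = rewardToneKHz, punishToneKHz = punishToneKHz,
      frameRateNeural = frameRateNeural, frameRateVideo = frameRateVideo)
}

nTrials <- function(design) {
  design@nReward + design@nRewardCatch + design@nPunish + design@nPunishCatch
}

setMethod("show", "SessionDesign", function(object) {
  cat("SessionDesign:", nTrials(object), "trials (",
      object@nReward, "reward /", object@nRewardCatch, "reward catch /",
      object@nPunish, "punish /", object@nPunishCatch, "punish catch )\n")
  cat("  CS", object@csDuration, "s, US delay", object@usDelay,
      "s, ITI", object@itiRange[1], "-", object@itiRange[2], "s\n")
  cat("  tones", object@rewardToneKHz, "/", object@punishToneKHz,
      "kHz; imaging", object@frameRateNeural, "Hz; video",
      object@frameRateVideo, "fps\n")
})

# ---------------------------------------------------------------------------
# Phenotype specification (planted effects)
# ---------------------------------------------------------------------------

#' @rdname PhenotypeSpec
#' @export
setClass("PhenotypeSpec", representation(
  label = "character",
  sptMeanByEpoch = "numeric", sptSd = "numeric",
  rewardGainByEpoch = "numeric", punishGainByEpoch = "numeric",
  facialAmpByEpoch = "numeric",
  lickAnticipatoryRate = "numeric", lickConsummatoryRate = "numeric"
))

setValidity("PhenotypeSpec", function(object) {
  msg <- character()
  ep <- cmsEpochs()
  for (s in c("sptMeanByEpoch", "rewardGainByEpoch", "punishGainByEpoch",
              "facialAmpByEpoch")) {
    v <- slot(object, s)
    if (!all(ep %in% names(v)))
      msg <- c(msg, paste0(s, " must name every epoch in cmsEpochs()"))
    if (any(v < 0)) msg <- c(msg, paste0(s, " must be non-negative"))
  }
  if (any(object@sptMeanByEpoch < 0 | object@sptMeanByEpoch > 100))
    msg <- c(msg, "sptMeanByEpoch must lie in [0, 100]")
  if (object@sptSd < 0) msg <- c(msg, "sptSd must be >= 0")
  if (object@lickAnticipatoryRate < 0 || object@lickConsummatoryRate < 0)
    msg <- c(msg, "lick rates must be >= 0")
  if (!object@label %in% phenotypeLevels())
    msg <- c(msg, "label must be one of control/resilient/susceptible/neutral")
  if (length(msg)) msg else TRUE
})

#' Planted per-phenotype effect specification
#'
#' A `PhenotypeSpec` declares, per epoch, the ground-truth behavioral and
#' physiological parameters the synthetic cohort generator plants for one
#' phenotype: the mean (and sd) of the sucrose-preference score, the
#' multiplicative gain on the neural reward-US and punishment-US responses,
#' the multiplicative amplitude on the event-locked facial displacement, and
#' the anticipatory/consummatory lick rates.
#'
#' @param label One of `"control"`, `"resilient"`, `"susceptible"`, `"neutral"`.
#' @param sptMeanByEpoch,rewardGainByEpoch,punishGainByEpoch,facialAmpByEpoch
#'   Named numeric vectors covering every epoch in [cmsEpochs()].
#' @param sptSd Sucrose-preference sd (percentage points).
#' @param lickAnticipatoryRate,lickConsummatoryRate Lick rates (Hz) active
#'   between CS and US onset, and after reward US delivery, respectively.
#'
#' @return A `PhenotypeSpec`.
#' @seealso [defaultPhenotypeSpecs()] for the stock cohort conditions.
#' @export
phenotypeSpec <- function(label, sptMeanByEpoch, sptSd = 4,
                          rewardGainByEpoch, punishGainByEpoch,
                          facialAmpByEpoch,
                          lickAnticipatoryRate = 2.5,
                          lickConsummatoryRate = 6) {
  new("PhenotypeSpec", label = label,
      sptMeanByEpoch = sptMeanByEpoch, sptSd = sptSd,
      rewardGainByEpoch = rewardGainByEpoch,
      punishGainByEpoch = punishGainByEpoch,
      facialAmpByEpoch = facialAmpByEpoch,
      lickAnticipatoryRate = lickAnticipatoryRate,
      lickConsummatoryRate = lickConsummatoryRate)
}

byEpoch <- function(...) {
  ## helper: build a full named epoch vector from (epoch = value) pairs,
  ## filling unnamed epochs with `default`
  args <- list(...)
  default <- if (is.null(args$default)) 1 else args$default
  args$default <- NULL
  v <- stats::setNames(rep(default, length(cmsEpochs())), cmsEpochs())
  for (nm in names(args)) v[nm] <- args[[nm]]
  v
}

# ---------------------------------------------------------------------------
# Cohort configuration
# ---------------------------------------------------------------------------

#' @rdname CohortConfig
#' @export
setClass("CohortConfig", representation(
  nControl = "integer", nResilient = "integer", nSusceptible = "integer",
  nNeutral = "integer",
  nNeuronsPerMouse = "integer", roiMatchFraction = "numeric",
  epochs = "character",
  noiseSdNeural = "numeric", keypointJitterSd = "numeric",
  calciumDecayTau = "numeric", seed = "integer",
  design = "SessionDesign", phenotypes = "list"
))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nControl <= 0L || object@nResilient <= 0L || object@nSusceptible <= 0L)
    msg <- c(msg, "nControl, nResilient and nSusceptible must be > 0")
  if (object@nNeutral < 0L) msg <- c(msg, "nNeutral must be >= 0")
  if (object@nNeuronsPerMouse <= 0L) msg <- c(msg, "nNeuronsPerMouse must be > 0")
  if (object@roiMatchFraction <= 0 || object@roiMatchFraction > 1)
    msg <- c(msg, "roiMatchFraction must lie in (0, 1]")
  if (!all(object@epochs %in% cmsEpochs()))
    msg <- c(msg, "epochs must be a subset of cmsEpochs()")
  if (object@calciumDecayTau <= 0) msg <- c(msg, "calciumDecayTau must be > 0")
  if (object@noiseSdNeural < 0) msg <- c(msg, "noiseSdNeural must be >= 0")
  if (object@keypointJitterSd < 0) msg <- c(msg, "keypointJitterSd must be >= 0")
  needed <- c("control", "resilient", "susceptible",
              if (object@nNeutral > 0L) "neutral")
  if (!all(needed %in% names(object@phenotypes)))
    msg <- c(msg, "phenotypes must name a PhenotypeSpec for every generated group")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort configuration
#'
#' Sizes, noise levels and timeline of a synthetic chronic-mild-stress cohort.
#' Defaults emulate the study cohort: 14 non-stressed controls and 8 stressed
#' mice split into resilient and susceptible groups, one session per epoch
#' over the ten-week timeline, with a GCaMP7f-like single-exponential calcium
#' kernel (tau = 0.7 s).
#'
#' @param nControl,nResilient,nSusceptible,nNeutral Group sizes. The neutral
#'   group is off by default and exists to exercise k = 3 clustering.
#' @param nNeuronsPerMouse Neurons recorded per session.
#' @param roiMatchFraction Fraction of cells tracked across consecutive
#'   sessions (in (0, 1]).
#' @param epochs Ordered subset of [cmsEpochs()] to simulate.
#' @param noiseSdNeural Additive Gaussian noise sd of the activity traces
#'   (z units).
#' @param keypointJitterSd Facial keypoint jitter sd (px).
#' @param calciumDecayTau Calcium kernel decay constant (s).
#' @param seed Integer master seed; every session derives its own stream.
#' @param design A [sessionDesign()].
#' @param phenotypes Named list of [phenotypeSpec()] objects, one per group;
#'   defaults to [defaultPhenotypeSpecs()].
#'
#' @return A `CohortConfig`.
#' @export
cohortConfig <- function(nControl = 14L, nResilient = 4L, nSusceptible = 4L,
                         nNeutral = 0L,
                         nNeuronsPerMouse = 80L, roiMatchFraction = 0.7,
                         epochs = cmsEpochs(),
                         noiseSdNeural = 1, keypointJitterSd = 2,
                         calciumDecayTau = 0.7, seed = 1L,
                         design = sessionDesign(),
                         phenotypes = defaultPhenotypeSpecs()) {
  new("CohortConfig",
      nControl = as.integer(nControl), nResilient = as.integer(nResilient),
      nSusceptible = as.integer(nSusceptible), nNeutral = as.integer(nNeutral),
      nNeuronsPerMouse = as.integer(nNeuronsPerMouse),
      roiMatchFraction = roiMatchFraction, epochs = epochs,
      noiseSdNeural = noiseSdNeural, keypointJitterSd = keypointJitterSd,
      calciumDecayTau = calciumDecayTau, seed = as.integer(seed),
      design = design, phenotypes = phenotypes)
}

# ---------------------------------------------------------------------------
# Neural containers
# ---------------------------------------------------------------------------

#' NeuralSession: one imaging session as a SummarizedExperiment
#'
#' Rows are neurons (ROIs), columns are imaging frames. The single assay
#' `"activity"` holds fluorescence (or z-scored) traces; `rowData` carries
#' the ROI identifiers and `metadata` the frame rate, mouse id and epoch.
#'
#' @rdname NeuralSession
#' @export
setClass("NeuralSession", contains = "SummarizedExperiment")

setValidity("NeuralSession", function(object) {
  msg <- character()
  md <- metadata(object)
  if (is.null(md$frame_rate) || md$frame_rate <= 0)
    msg <- c(msg, "metadata frame_rate must be set and > 0")
  if (is.null(md$mouse_id) || is.null(md$epoch))
    msg <- c(msg, "metadata mouse_id and epoch must be set")
  ids <- rowData(object)$roi_id
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "rowData roi_id must exist and be unique within a session")
  if (!"activity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'activity' is required")
  if (length(msg)) msg else TRUE
})

#' @param activity Numeric matrix, neurons x frames.
#' @param frameRate Imaging frame rate (Hz).
#' @param roiIds Unique ROI identifiers (default `roi_1 ... roi_n`).
#' @param mouseId,epoch Session identity tags.
#' @return `neuralSession()` returns a `NeuralSession`.
#' @rdname NeuralSession
#' @export
neuralSession <- function(activity, frameRate, roiIds = NULL,
                          mouseId = "m1", epoch = "baseline") {
  activity <- as.matrix(activity)
  if (is.null(roiIds)) roiIds <- paste0("roi_", seq_len(nrow(activity)))
  se <- SummarizedExperiment(
    assays = list(activity = activity),
    rowData = DataFrame(roi_id = as.character(roiIds)),
    metadata = list(frame_rate = frameRate, mouse_id = mouseId, epoch = epoch))
  rownames(se) <- as.character(roiIds)
  new("NeuralSession", se)
}

#' @param session,x A `NeuralSession`.
#' @rdname NeuralSession
#' @export
activityMatrix <- function(session) assay(session, "activity")

#' @rdname NeuralSession
#' @export
frameRate <- function(session) metadata(session)$frame_rate

#' @rdname NeuralSession
#' @export
roiIds <- function(session) rowData(session)$roi_id

#' @rdname NeuralSession
#' @export
mouseId <- function(session) metadata(session)$mouse_id

#' @rdname NeuralSession
#' @export
epochOf <- function(session) metadata(session)$epoch

setMethod("show", "NeuralSession", function(object) {
  cat("NeuralSession:", nrow(object), "neurons x", ncol(object), "frames @",
      round(frameRate(object), 2), "Hz  (mouse", mouseId(object),
      ", epoch", paste0(epochOf(object), ")\n"))
})

# ---------------------------------------------------------------------------
# Event-aligned tensor
# ---------------------------------------------------------------------------

#' @rdname EventAlignedTensor
#' @export
setClass("EventAlignedTensor", representation(
  data = "array",          # units x bins x trials
  binWidth = "numeric",
  window = "numeric",      # (start, end) s relative to the event
  event = "character",
  zMode = "character",     # "raw", "local", "superglobal"
  flooredSd = "matrix",    # units x trials: TRUE where the baseline sd was floored
  nDropped = "integer"     # trials dropped because the window left the recording
))

setValidity("EventAlignedTensor", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be a units x bins x trials array")
  span <- diff(object@window)
  nb <- span / object@binWidth
  if (abs(nb - round(nb)) > 1e-8)
    msg <- c(msg, "window span must be an integer number of bins")
  else if (length(d) == 3L && d[2] != round(nb))
    msg <- c(msg, "bin dimension must equal window span / binWidth")
  if (length(msg)) msg else TRUE
})

#' Event-aligned response tensor
#'
#' Units (neurons or facial feature channels) x time bins x trials, aligned
#' to a task event with a fixed peri-event window binned at `binWidth`
#' (100 ms by default). Bins are half-open `[t, t + binWidth)`; bin centers
#' are reported by [binCenters()].
#'
#' @param data units x bins x trials numeric array.
#' @param binWidth Bin width (s).
#' @param window `(start, end)` window relative to the event (s).
#' @param event Event label.
#' @param zMode Normalization applied: `"raw"`, `"local"` or `"superglobal"`.
#' @param flooredSd Optional units x trials logical matrix flagging floored
#'   baseline standard deviations.
#' @param nDropped Number of trials dropped during alignment.
#' @return An `EventAlignedTensor`.
#' @export
eventAlignedTensor <- function(data, binWidth = 0.1, window = c(-10, 10),
                               event = "event", zMode = "raw",
                               flooredSd = NULL, nDropped = 0L) {
  if (is.null(flooredSd))
    flooredSd <- matrix(FALSE, dim(data)[1], dim(data)[3])
  new("EventAlignedTensor", data = data, binWidth = binWidth,
      window = as.numeric(window), event = event, zMode = zMode,
      flooredSd = flooredSd, nDropped = as.integer(nDropped))
}

#' @param x An `EventAlignedTensor` or `Trajectory`.
#' @return `binCenters()` returns the bin-center times (s).
#' @rdname eventAlignedTensor
#' @export
binCenters <- function(x) {
  nb <- if (is(x, "EventAlignedTensor")) dim(x@data)[2] else nrow(x@points)
  x@window[1] + (seq_len(nb) - 0.5) * x@binWidth
}

#' @return `tensorData()` returns the underlying units x bins x trials array.
#' @rdname eventAlignedTensor
#' @export
tensorData <- function(x) x@data

#' @return `trialMean()` returns the units x bins trial-average matrix.
#' @rdname eventAlignedTensor
#' @export
trialMean <- function(x) {
  apply(x@data, c(1, 2), mean)
}

setMethod("show", "EventAlignedTensor", function(object) {
  d <- dim(object@data)
  cat("EventAlignedTensor [", object@event, "]: ", d[1], " units x ", d[2],
      " bins x ", d[3], " trials; window ", object@window[1], "..",
      object@window[2], " s, bin ", object@binWidth * 1000, " ms, z-mode '",
      object@zMode, "'\n", sep = "")
  if (object@nDropped > 0L)
    cat("  ", object@nDropped, "trial(s) dropped during alignment\n")
})

# ---------------------------------------------------------------------------
# PCA model + trajectory
# ---------------------------------------------------------------------------

#' @rdname PCModel
#' @export
setClass("PCModel", representation(
  loadings = "matrix",     # units x components, orthonormal columns
  variances = "numeric",   # per-component variance, non-increasing
  totalVariance = "numeric",
  center = "numeric"       # per-unit centering vector
))

setValidity("PCModel", function(object) {
  msg <- character()
  if (length(object@variances) != ncol(object@loadings))
    msg <- c(msg, "one variance per component is required")
  if (is.unsorted(-object@variances))
    msg <- c(msg, "component variances must be non-increasing")
  if (length(object@center) != nrow(object@loadings))
    msg <- c(msg, "center must have one entry per unit")
  cp <- crossprod(object@loadings)
  if (max(abs(cp - diag(ncol(object@loadings)))) > 1e-6)
    msg <- c(msg, "loadings must be orthonormal")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PCModel", function(object) {
  cat("PCModel:", nrow(object@loadings), "units,", ncol(object@loadings),
      "components\n")
  fr <- object@variances / object@totalVariance
  k <- min(5L, length(fr))
  cat("  variance fractions:", paste(sprintf("%.3f", fr[seq_len(k)]),
                                     collapse = " "),
      if (length(fr) > k) "...\n" else "\n")
})

#' @param model A `PCModel`.
#' @return Per-component explained-variance fractions (sum to 1 over all
#'   components).
#' @rdname fitPCA
#' @export
varianceFractions <- function(model) model@variances / model@totalVariance

#' @rdname Trajectory
#' @export
setClass("Trajectory", representation(
  points = "matrix",       # bins x n_pcs
  binWidth = "numeric",
  window = "numeric",
  label = "character"
))

setValidity("Trajectory", function(object) {
  if (any(!is.finite(object@points))) "trajectory points must be finite" else TRUE
})

#' @param traj,object A `Trajectory`.
#' @return `trajectoryPoints()` returns the bins x PCs coordinate matrix.
#' @rdname Trajectory
#' @export
trajectoryPoints <- function(traj) traj@points

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory [", object@label, "]: ", nrow(object@points), " bins x ",
      ncol(object@points), " PCs over ", object@window[1], "..",
      object@window[2], " s\n", sep = "")
})

# ---------------------------------------------------------------------------
# Facial containers
# ---------------------------------------------------------------------------

#' @rdname FacialSkeleton
#' @export
setClass("FacialSkeleton", representation(
  nodes = "character",
  regions = "list",        # named list of node-name vectors (>= 3 each)
  angleTriples = "list",   # named list of node-name triples, vertex = middle
  kinematicNodes = "list"  # named list: node name(s) whose centroid is tracked
))

setValidity("FacialSkeleton", function(object) {
  msg <- character()
  if (anyDuplicated(object@nodes)) msg <- c(msg, "node names must be unique")
  for (rn in names(object@regions)) {
    r <- object@regions[[rn]]
    if (length(r) < 3L) msg <- c(msg, paste0("region '", rn, "' needs >= 3 nodes"))
    if (!all(r %in% object@nodes))
      msg <- c(msg, paste0("region '", rn, "' cites unknown nodes"))
  }
  for (an in names(object@angleTriples)) {
    a <- object@angleTriples[[an]]
    if (length(a) != 3L || !all(a %in% object@nodes))
      msg <- c(msg, paste0("angle '", an, "' must be a triple of known nodes"))
  }
  for (kn in names(object@kinematicNodes)) {
    if (!all(object@kinematicNodes[[kn]] %in% object@nodes))
      msg <- c(msg, paste0("kinematic target '", kn, "' cites unknown nodes"))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname KeypointTrack
#' @export
setClass("KeypointTrack", representation(
  coords = "array",        # frames x nodes x (x, y, confidence)
  nodes = "character",
  fps = "numeric",
  pxPerCm = "numeric"      # NA until calibrated
))

setValidity("KeypointTrack", function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "coords must be frames x nodes x (x, y, confidence)")
  else if (d[2] != length(object@nodes))
    msg <- c(msg, "node dimension must match the node-name list")
  if (object@fps <= 0) msg <- c(msg, "fps must be > 0")
  if (length(msg)) msg else TRUE
})

#' Keypoint track container
#'
#' Facial pose-track time series: frames x nodes x (x, y, confidence), with
#' the node-name list, video frame rate, and an optional px-per-cm
#' calibration factor set by [calibrateTrack()].
#'
#' @param coords frames x nodes x 3 array (x px, y px, confidence in 0..1).
#' @param nodes Node names (defaults to the 13-point facial skeleton).
#' @param fps Video frame rate.
#' @param pxPerCm Calibration factor; `NA` while uncalibrated.
#' @return A `KeypointTrack`.
#' @export
keypointTrack <- function(coords, nodes = facialSkeleton()@nodes, fps = 30,
                          pxPerCm = NA_real_) {
  new("KeypointTrack", coords = coords, nodes = nodes, fps = fps,
      pxPerCm = pxPerCm)
}

setMethod("show", "KeypointTrack", function(object) {
  cat("KeypointTrack:", dim(object@coords)[1], "frames x",
      length(object@nodes), "nodes @", object@fps, "fps;",
      if (is.na(object@pxPerCm)) "uncalibrated\n"
      else paste0(round(object@pxPerCm, 2), " px/cm\n"))
})

#' @rdname FacialFeatureMatrix
#' @export
setClass("FacialFeatureMatrix", representation(
  values = "matrix",       # channels x frames
  channelInfo = "DataFrame",  # kind, units per channel
  fps = "numeric"
))

setValidity("FacialFeatureMatrix", function(object) {
  msg <- character()
  if (nrow(object@channelInfo) != nrow(object@values))
    msg <- c(msg, "one channelInfo row per feature channel is required")
  ok <- c(distance = "cm", angle = "deg", velocity = "cm/s",
          acceleration = "cm/s^2", area = "cm^2")
  kind <- object@channelInfo$kind
  units <- object@channelInfo$units
  if (!all(kind %in% names(ok)))
    msg <- c(msg, "channel kind must be distance/angle/velocity/acceleration/area")
  else if (!all(units == ok[kind]))
    msg <- c(msg, "channel units must be consistent with kind")
  ang <- object@values[kind == "angle", , drop = FALSE]
  if (length(ang) && (min(ang, na.rm = TRUE) < -1e-9 ||
                      max(ang, na.rm = TRUE) > 180 + 1e-9))
    msg <- c(msg, "angles must lie in [0, 180] degrees")
  if (length(msg)) msg else TRUE
})

#' @param x A `FacialFeatureMatrix`.
#' @return `featureValues()` returns the channels x frames matrix;
#'   `channelInfo()` its per-channel metadata (name, kind, units).
#' @rdname extractFacialFeatures
#' @export
featureValues <- function(x) x@values

#' @rdname extractFacialFeatures
#' @export
channelInfo <- function(x) x@channelInfo

setMethod("show", "FacialFeatureMatrix", function(object) {
  cat("FacialFeatureMatrix:", nrow(object@values), "channels x",
      ncol(object@values), "frames @", object@fps, "fps\n")
  print(table(object@channelInfo$kind))
})

# ---------------------------------------------------------------------------
# Phenotype assignment
# ---------------------------------------------------------------------------

#' @rdname PhenotypeAssignment
#' @export
setClass("PhenotypeAssignment", representation(
  table = "data.frame",    # mouse_id, label, cluster
  clusterMeans = "numeric",
  kSelected = "integer",
  wcss = "numeric"         # per-k WCSS curve (k = 1..k_max), possibly empty
))

setValidity("PhenotypeAssignment", function(object) {
  msg <- character()
  if (!all(c("mouse_id", "label", "cluster") %in% names(object@table)))
    msg <- c(msg, "table must have mouse_id, label and cluster columns")
  if (!all(object@table$label %in% phenotypeLevels()))
    msg <- c(msg, "labels must be control/resilient/susceptible/neutral")
  cm <- object@clusterMeans
  if (length(cm) > 1L && is.unsorted(cm, strictly = TRUE))
    msg <- c(msg, "cluster means must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' @param x A `PhenotypeAssignment`.
#' @return `assignmentTable()` returns the mouse_id/label/cluster data frame.
#' @rdname assignPhenotypes
#' @export
assignmentTable <- function(x) x@table

setMethod("show", "PhenotypeAssignment", function(object) {
  cat("PhenotypeAssignment (k =", object@kSelected, "):\n")
  print(table(object@table$label))
})

# ---------------------------------------------------------------------------
# Decoding result
# ---------------------------------------------------------------------------

#' @rdname DecodingResult
#' @export
setClass("DecodingResult", representation(
  comparison = "character",
  aucPerBin = "matrix",      # bins x folds
  shuffleAucPerBin = "matrix",  # bins x permutations (0 columns if absent)
  nPcsUsed = "integer",
  nFolds = "integer",
  binTimes = "numeric",
  smoothed = "logical"
))

setValidity("DecodingResult", function(object) {
  msg <- character()
  a <- object@aucPerBin
  if (length(a) && any(!is.na(a)) &&
      (min(a, na.rm = TRUE) < -1e-9 || max(a, na.rm = TRUE) > 1 + 1e-9))
    msg <- c(msg, "AUC values must lie in [0, 1]")
  if (ncol(object@aucPerBin) != object@nFolds)
    msg <- c(msg, "fold count must match the configured number of folds")
  if (length(msg)) msg else TRUE
})

#' @param x A `DecodingResult`.
#' @return `aucPerBin()` returns the bins x folds AUC matrix; `meanAuc()` the
#'   per-bin mean over folds; `shuffleAucPerBin()` the bins x permutations
#'   null matrix.
#' @rdname decodeTimecourse
#' @export
aucPerBin <- function(x) x@aucPerBin

#' @rdname decodeTimecourse
#' @export
meanAuc <- function(x) rowMeans(x@aucPerBin)

#' @rdname decodeTimecourse
#' @export
shuffleAucPerBin <- function(x) x@shuffleAucPerBin

setMethod("show", "DecodingResult", function(object) {
  cat("DecodingResult [", object@comparison, "]: ", nrow(object@aucPerBin),
      " bins x ", object@nFolds, " folds, ", object@nPcsUsed, " PCs",
      if (object@smoothed) ", smoothed" else "", "\n", sep = "")
  cat("  mean AUC over bins:", sprintf("%.3f", mean(object@aucPerBin)), "\n")
  if (ncol(object@shuffleAucPerBin))
    cat("  shuffle null mean:",
        sprintf("%.3f", mean(object@shuffleAucPerBin)), "\n")
})

# ---------------------------------------------------------------------------
# Synthetic cohort
# ---------------------------------------------------------------------------

#' @rdname SyntheticCohort
#' @export
setClass("SyntheticCohort", representation(
  config = "CohortConfig",
  mice = "data.frame",       # mouse_id, group_raw, phenotype (ground truth)
  behavior = "data.frame",   # mouse_id, epoch, sucrose_licks, water_licks,
                             # spt_percent, tst_mobility_s, social_index
  sessionSeeds = "matrix"    # mice x epochs integer seeds
))

#' @param cohort,object A `SyntheticCohort`.
#' @return `cohortMice()` returns the mouse table with ground-truth phenotype
#'   labels; `cohortBehavior()` the weekly behavioral score table;
#'   `nSessions()` the number of (mouse, epoch) sessions the cohort defines.
#' @rdname generateCohort
#' @export
cohortMice <- function(cohort) cohort@mice

#' @rdname generateCohort
#' @export
cohortBehavior <- function(cohort) cohort@behavior

#' @rdname generateCohort
#' @export
nSessions <- function(cohort) nrow(cohort@mice) * length(cohort@config@epochs)

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", nrow(object@mice), "mice x",
      length(object@config@epochs), "epochs (", nSessions(object),
      "sessions )\n")
  print(table(object@mice$phenotype))
})
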