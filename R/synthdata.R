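## Synthetic cohort generator.
##
## Emulates the raw outputs of a longitudinal chronic-mild-stress experiment:
## weekly behavioral scores, Pavlovian discrimination trial tables and lick
## trains, calcium-imaging activity matrices with cross-session cell
## identity, and facial keypoint tracks. Effects (sucrose-preference drops,
## reward/punishment response gains, facial displacement amplitudes) are
## planted per phenotype and epoch through PhenotypeSpec objects so that
## every downstream analysis stage has a known ground truth.

#' Stock phenotype specifications
#'
#' The default planted conditions, one [phenotypeSpec()] per group:
#'
#' * `control` -- sucrose preference stable near 85%; the neural reward-US
#'   gain ramps from 1.0 at baseline to 1.5 by the final stress week and
#'   stays there (reward processing strengthens over time in unstressed
#'   animals).
#' * `resilient` -- preference stays high under stress; reward gain flat at
#'   1.0 through stress, rising only after ketamine; facial amplitude dips
#'   at the ketamine/post-ketamine epochs.
#' * `susceptible` -- preference declines across stress weeks to ~55% at the
#'   post-stress time point and recovers after ketamine; reward gain is
#'   elevated (1.3) already at baseline and flat through stress, rising
#'   after ketamine; facial amplitude is low at baseline and high post-stress.
#' * `neutral` -- intermediate preference (~72% post-stress); only generated
#'   when a cohort requests a neutral group.
#'
#' Punishment-US gains are 1.0 for every group and epoch.
#'
#' @return Named list of `PhenotypeSpec` objects.
#' @export
defaultPhenotypeSpecs <- function() {
  ones <- byEpoch(default = 1)
  list(
    control = phenotypeSpec(
      label = "control",
      sptMeanByEpoch = byEpoch(default = 85),
      rewardGainByEpoch = byEpoch(default = 1,
        stress_w1 = 1.08, stress_w2 = 1.17, stress_w3 = 1.25,
        stress_w4 = 1.33, stress_w5 = 1.42, stress_w6 = 1.5,
        saline = 1.5, ketamine = 1.5, post_ketamine = 1.5),
      punishGainByEpoch = ones,
      facialAmpByEpoch = ones,
      lickAnticipatoryRate = 2.5, lickConsummatoryRate = 6),
    resilient = phenotypeSpec(
      label = "resilient",
      sptMeanByEpoch = byEpoch(default = 85, stress_w5 = 83, stress_w6 = 83),
      rewardGainByEpoch = byEpoch(default = 1, ketamine = 1.2,
                                  post_ketamine = 1.4),
      punishGainByEpoch = ones,
      facialAmpByEpoch = byEpoch(default = 1, stress_w2 = 1.3, stress_w5 = 1.3,
                                 stress_w6 = 1.3, ketamine = 0.6,
                                 post_ketamine = 0.6),
      lickAnticipatoryRate = 2.5, lickConsummatoryRate = 6),
    susceptible = phenotypeSpec(
      label = "susceptible",
      sptMeanByEpoch = byEpoch(default = 80,
        baseline = 85, stress_w1 = 80, stress_w2 = 75, stress_w3 = 70,
        stress_w4 = 65, stress_w5 = 60, stress_w6 = 55, saline = 58,
        ketamine = 80, post_ketamine = 80),
      rewardGainByEpoch = byEpoch(default = 1.3, ketamine = 1.5,
                                  post_ketamine = 1.7),
      punishGainByEpoch = ones,
      facialAmpByEpoch = byEpoch(default = 1,
        baseline = 0.5, stress_w4 = 1.3, stress_w5 = 1.5, stress_w6 = 1.6,
        saline = 1.4, ketamine = 1.2, post_ketamine = 1.5),
      lickAnticipatoryRate = 1.2, lickConsummatoryRate = 4),
    neutral = phenotypeSpec(
      label = "neutral",
      sptMeanByEpoch = byEpoch(default = 78,
        stress_w4 = 75, stress_w5 = 73, stress_w6 = 72),
      rewardGainByEpoch = ones, punishGainByEpoch = ones,
      facialAmpByEpoch = ones,
      lickAnticipatoryRate = 2, lickConsummatoryRate = 5)
  )
}

# ---------------------------------------------------------------------------
# Trial sequence pseudorandomization
# ---------------------------------------------------------------------------

## Draw one trial-type sequence satisfying the protocol constraints:
## the first 3 trials are reward trials, no run of 3 consecutive punishment
## trials, catch trials confined to the last 15% of the sequence, and the
## remaining trials pseudorandomized across the two half-session blocks.
## Uses the caller's RNG stream.
drawTrialSequence <- function(design, maxTries = 1000L) {
  n <- nTrials(design)
  nCatch <- design@nRewardCatch + design@nPunishCatch
  catchZone <- seq.int(floor(0.85 * n) + 1L, n)
  if (length(catchZone) < nCatch)
    stopf("infeasible pseudorandomization: %d catch trials but only %d slots in the last 15%% of %d trials",
          nCatch, length(catchZone), n)
  nRewardFree <- design@nReward - 3L
  half <- n %/% 2L
  isPunishType <- function(types) types %in% c("punish", "punish_catch")
  for (i in seq_len(maxTries)) {
    types <- rep(NA_character_, n)
    types[1:3] <- "reward"
    catchPos <- sample(catchZone, nCatch)
    types[catchPos] <- sample(rep(c("reward_catch", "punish_catch"),
                                  c(design@nRewardCatch, design@nPunishCatch)))
    free <- which(is.na(types))
    freeB1 <- free[free <= half]
    freeB2 <- free[free > half]
    ## balance punishment trials across the two blocks
    nP1 <- min(design@nPunish %/% 2L + sample(0:(design@nPunish %% 2L), 1L),
               length(freeB1))
    nP2 <- design@nPunish - nP1
    if (nP2 > length(freeB2)) next
    fill <- rep("reward", length(free))
    names(fill) <- free
    fill[as.character(sample(freeB1, nP1))] <- "punish"
    fill[as.character(sample(freeB2, nP2))] <- "punish"
    types[free] <- fill[as.character(free)]
    runs <- rle(isPunishType(types))
    if (any(runs$values & runs$lengths >= 3L)) next
    return(types)
  }
  stopf("infeasible pseudorandomization: no valid trial ordering found in %d tries",
        maxTries)
}

## Assemble the trial table (types, CS/US onsets, tones) for one session.
## Timing: the first CS starts after a 15-s pre-roll so that -10 s windows
## stay inside the recording; ITIs are uniform in the configured range.
drawTrialTable <- function(design) {
  types <- drawTrialSequence(design)
  n <- length(types)
  iti <- stats::runif(n - 1L, design@itiRange[1], design@itiRange[2])
  cs <- 15 + c(0, cumsum(design@csDuration + iti))
  us <- ifelse(types %in% c("reward", "punish"), cs + design@usDelay, NA_real_)
  tone <- ifelse(startsWith(types, "reward"), design@rewardToneKHz,
                 design@punishToneKHz)
  data.frame(trial_index = seq_len(n), type = types,
             cs_onset_s = cs, us_onset_s = us, tone_khz = tone)
}

sessionDuration <- function(trials, design) {
  max(trials$cs_onset_s) + design@csDuration + 15
}

# ---------------------------------------------------------------------------
# Licks
# ---------------------------------------------------------------------------

## Inhomogeneous Bernoulli-per-frame lick process on the video frame grid.
## Anticipatory licking in [CS onset, US onset) of reward and reward-catch
## trials; consummatory licking in [US onset, CS offset + 3 s] of reward
## trials only; rate zero elsewhere.
drawLickTrain <- function(trials, design, phen) {
  fps <- design@frameRateVideo
  dur <- sessionDuration(trials, design)
  t <- seq(0, dur, by = 1 / fps)
  rate <- numeric(length(t))
  for (i in seq_len(nrow(trials))) {
    cs <- trials$cs_onset_s[i]
    if (startsWith(trials$type[i], "reward")) {
      antic <- t >= cs & t < cs + design@usDelay
      rate[antic] <- phen@lickAnticipatoryRate
      if (trials$type[i] == "reward") {
        us <- trials$us_onset_s[i]
        cons <- t >= us & t <= cs + design@csDuration + 3
        rate[cons] <- phen@lickConsummatoryRate
      }
    }
  }
  p <- pmin(rate / fps, 1)
  t[stats::runif(length(t)) < p]
}

# ---------------------------------------------------------------------------
# Neural activity
# ---------------------------------------------------------------------------

## Per-neuron event-response amplitudes for the four planted event kinds.
## Rectified Gaussians: most cells respond, a minority are silent for a
## given event. Drawn once per mouse so cells keep their identity across
## sessions.
drawAmplitudes <- function(nNeurons) {
  cbind(reward_cs = pmax(0, stats::rnorm(nNeurons, 0.8, 0.6)),
        reward_us = pmax(0, stats::rnorm(nNeurons, 1.5, 1.0)),
        punish_cs = pmax(0, stats::rnorm(nNeurons, 0.8, 0.6)),
        punish_us = pmax(0, stats::rnorm(nNeurons, 1.5, 1.0)))
}

## Event impulse trains on the imaging frame grid, one column per event
## kind, with the phenotype/epoch gains folded into the US impulses and a
## lognormal per-trial amplitude jitter shared across neurons.
eventImpulses <- function(trials, nFrames, frameRate, rewardGain, punishGain,
                          trialJitterSdLog = 0.25) {
  imp <- matrix(0, nFrames, 4,
                dimnames = list(NULL, c("reward_cs", "reward_us",
                                        "punish_cs", "punish_us")))
  addAt <- function(times, col, gain) {
    times <- times[!is.na(times)]
    if (!length(times)) return()
    f <- pmin(nFrames, floor(times * frameRate) + 1L)
    jit <- stats::rlnorm(length(f), 0, trialJitterSdLog)
    for (k in seq_along(f)) imp[f[k], col] <<- imp[f[k], col] + gain * jit[k]
  }
  rw <- startsWith(trials$type, "reward")
  addAt(trials$cs_onset_s[rw], "reward_cs", rewardGain)
  addAt(trials$us_onset_s[trials$type == "reward"], "reward_us", rewardGain)
  addAt(trials$cs_onset_s[!rw], "punish_cs", punishGain)
  addAt(trials$us_onset_s[trials$type == "punish"], "punish_us", punishGain)
  imp
}

## Convolve impulse trains with a causal single-exponential calcium kernel.
expKernelFilter <- function(impulses, frameRate, tau) {
  a <- exp(-1 / (frameRate * tau))
  apply(impulses, 2, function(x) as.numeric(stats::filter(x, a, "recursive")))
}

drawNeuralSession <- function(trials, design, phen, epoch, amplitudes,
                              noiseSd, tau, mouseIdTag) {
  fr <- design@frameRateNeural
  nFrames <- ceiling(sessionDuration(trials, design) * fr)
  imp <- eventImpulses(trials, nFrames, fr,
                       rewardGain = phen@rewardGainByEpoch[[epoch]],
                       punishGain = phen@punishGainByEpoch[[epoch]])
  kernels <- expKernelFilter(imp, fr, tau)          # frames x 4
  signal <- amplitudes %*% t(kernels)               # neurons x frames
  if (noiseSd > 0)
    signal <- signal + matrix(stats::rnorm(length(signal), 0, noiseSd),
                              nrow(signal))
  neuralSession(signal, frameRate = fr,
                roiIds = paste0(mouseIdTag, "_", epoch, "_c",
                                seq_len(nrow(amplitudes))),
                mouseId = mouseIdTag, epoch = epoch)
}

# ---------------------------------------------------------------------------
# Facial keypoints
# ---------------------------------------------------------------------------

## Canonical rest pose of the 13-point facial skeleton (px), roughly a mouse
## profile: eye cluster upper-left, whisker stems mid-face, nose to the
## right, mouth/chin below.
restFacePose <- function() {
  m <- rbind(
    upper_eye = c(60, 40), lower_eye = c(60, 70),
    inner_eye = c(80, 55), outer_eye = c(40, 55),
    top_whisker_stem = c(120, 50), bottom_whisker_stem = c(120, 90),
    nose_upper = c(180, 40), nose_tip = c(205, 60),
    nostril_left = c(192, 52), nostril_right = c(198, 70),
    mouth_upper = c(175, 95), mouth_lower = c(172, 115),
    chin = c(160, 135))
  colnames(m) <- c("x", "y")
  m
}

## Per-mouse linear map from the 2 event-locked latents to keypoint
## displacements: nodes x (x, y) x latent, entries in px.
drawFaceMap <- function(nNodes = 13L, sdPx = 6) {
  array(stats::rnorm(nNodes * 2 * 2, 0, sdPx), dim = c(nNodes, 2, 2))
}

drawKeypointTrack <- function(trials, design, phen, epoch, faceMap,
                              jitterSd, tauFace = 0.3) {
  fps <- design@frameRateVideo
  nFrames <- ceiling(sessionDuration(trials, design) * fps)
  rest <- restFacePose()
  nNodes <- nrow(rest)
  ## two latents: one driven by reward events, one by punishment events
  imp <- eventImpulses(trials, nFrames, fps, rewardGain = 1, punishGain = 1)
  lat <- expKernelFilter(cbind(reward = imp[, "reward_cs"] + imp[, "reward_us"],
                               punish = imp[, "punish_cs"] + imp[, "punish_us"]),
                         fps, tauFace)
  amp <- phen@facialAmpByEpoch[[epoch]]
  coords <- array(NA_real_, c(nFrames, nNodes, 3))
  disp <- amp * (lat %*% rbind(as.vector(faceMap[, , 1]),
                               as.vector(faceMap[, , 2])))  # frames x (nodes*2)
  disp <- array(disp, c(nFrames, nNodes, 2))
  jit <- if (jitterSd > 0)
    array(stats::rnorm(nFrames * nNodes * 2, 0, jitterSd),
          c(nFrames, nNodes, 2)) else 0
  coords[, , 1] <- outer(rep(1, nFrames), rest[, "x"]) + disp[, , 1] +
    (if (is.array(jit)) jit[, , 1] else 0)
  coords[, , 2] <- outer(rep(1, nFrames), rest[, "y"]) + disp[, , 2] +
    (if (is.array(jit)) jit[, , 2] else 0)
  conf <- matrix(stats::runif(nFrames * nNodes, 0.85, 1), nFrames, nNodes)
  low <- stats::runif(nFrames * nNodes) < 0.002   # sporadic tracking dropouts
  conf[low] <- stats::runif(sum(low), 0, 0.4)
  coords[, , 3] <- conf
  keypointTrack(coords, nodes = rownames(rest), fps = fps)
}

# ---------------------------------------------------------------------------
# Session and cohort generation
# ---------------------------------------------------------------------------

#' Generate one synthetic Pavlovian discrimination session
#'
#' Draws a pseudorandomized trial table, a lick train, a neural activity
#' matrix and a facial keypoint track for one (mouse, epoch) session under a
#' fixed seed. Trial ordering satisfies the protocol constraints (first
#' three trials reward, no run of three punishment trials, catch trials in
#' the last 15% of the sequence). Neural traces are per-neuron event-response
#' amplitudes (scaled by the phenotype/epoch gain for US events) convolved
#' with a causal single-exponential calcium kernel plus Gaussian noise;
#' keypoints are a rest pose plus a two-latent event-locked displacement
#' scaled by the phenotype/epoch facial amplitude, plus jitter.
#'
#' @param design A [sessionDesign()].
#' @param phen A [phenotypeSpec()].
#' @param epoch Epoch tag (see [cmsEpochs()]).
#' @param seed Integer seed for this session.
#' @param nNeurons Number of neurons to simulate.
#' @param noiseSd Gaussian noise sd of the activity traces (z units).
#' @param tau Calcium kernel decay constant (s).
#' @param jitterSd Keypoint jitter sd (px).
#' @param mouseIdTag Mouse identifier embedded in ROI ids.
#' @param amplitudes Optional neurons x 4 amplitude matrix (reward_cs,
#'   reward_us, punish_cs, punish_us); drawn fresh when `NULL`. Pass the same
#'   matrix across epochs to keep cell identity.
#' @param faceMap Optional 13 x 2 x 2 latent-to-displacement map; drawn
#'   fresh when `NULL`.
#' @param withNeural,withKeypoints Toggle generation of the heavy components.
#'
#' @return A list with elements `trials` (data frame), `licks` (numeric
#'   timestamps, s), `neural` ([neuralSession()] or `NULL`) and `keypoints`
#'   ([keypointTrack()] or `NULL`).
#' @export
generateSession <- function(design, phen, epoch, seed,
                            nNeurons = 80L, noiseSd = 1, tau = 0.7,
                            jitterSd = 2, mouseIdTag = "m1",
                            amplitudes = NULL, faceMap = NULL,
                            withNeural = TRUE, withKeypoints = TRUE) {
  stopifnot(is(design, "SessionDesign"), is(phen, "PhenotypeSpec"))
  if (!epoch %in% cmsEpochs())
    stopf("unknown epoch '%s'", epoch)
  ## each component draws from its own derived stream so that toggling one
  ## component off cannot change the realization of another
  seed <- as.integer(seed)
  trials <- withr::with_seed(deriveSeed(seed, "trials"),
                             drawTrialTable(design))
  licks <- withr::with_seed(deriveSeed(seed, "licks"),
                            drawLickTrain(trials, design, phen))
  neural <- NULL
  if (withNeural) {
    if (is.null(amplitudes))
      amplitudes <- withr::with_seed(deriveSeed(seed, "amplitudes"),
                                     drawAmplitudes(nNeurons))
    neural <- withr::with_seed(deriveSeed(seed, "neural"),
      drawNeuralSession(trials, design, phen, epoch, amplitudes,
                        noiseSd, tau, mouseIdTag))
  }
  keypoints <- NULL
  if (withKeypoints) {
    if (is.null(faceMap))
      faceMap <- withr::with_seed(deriveSeed(seed, "facemap"), drawFaceMap())
    keypoints <- withr::with_seed(deriveSeed(seed, "keypoints"),
      drawKeypointTrack(trials, design, phen, epoch, faceMap, jitterSd))
  }
  list(trials = trials, licks = licks, neural = neural,
       keypoints = keypoints)
}

#' Generate a synthetic chronic-mild-stress cohort
#'
#' Builds the cohort skeleton -- ground-truth phenotype labels, weekly
#' behavioral scores (sucrose/water lick counts and the derived preference,
#' tail-suspension mobility, social index) and one deterministic seed per
#' (mouse, epoch) session. Heavy per-session data (trials, licks, neural
#' activity, keypoints) are materialized on demand by [cohortSession()] from
#' those seeds, so the same cohort object reproduces byte-identical sessions
#' on every access without holding the whole experiment in memory.
#'
#' @param config A [cohortConfig()].
#' @return A `SyntheticCohort`.
#' @examples
#' co <- generateCohort(cohortConfig(nControl = 2, nResilient = 2,
#'                                   nSusceptible = 2, seed = 1))
#' nSessions(co)
#' head(cohortBehavior(co))
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  counts <- c(control = config@nControl, resilient = config@nResilient,
              susceptible = config@nSusceptible, neutral = config@nNeutral)
  counts <- counts[counts > 0L]
  phen <- rep(names(counts), counts)
  ids <- sprintf("m%02d", seq_along(phen))
  mice <- data.frame(mouse_id = ids,
                     group_raw = ifelse(phen == "control", "control",
                                        "stressed"),
                     phenotype = phen, stringsAsFactors = FALSE)
  epochs <- config@epochs
  behavior <- withr::with_seed(deriveSeed(config@seed, "behavior"), {
    do.call(rbind, lapply(seq_len(nrow(mice)), function(i) {
      spec <- config@phenotypes[[mice$phenotype[i]]]
      do.call(rbind, lapply(epochs, function(ep) {
        p <- stats::rnorm(1, spec@sptMeanByEpoch[[ep]], spec@sptSd)
        p <- min(99, max(1, p)) / 100
        total <- round(stats::runif(1, 600, 1200))
        sucrose <- round(total * p)
        tst <- stats::rnorm(1, 110 +
          30 * (ep == "ketamine" && mice$group_raw[i] == "stressed"), 15)
        data.frame(mouse_id = mice$mouse_id[i], epoch = ep,
                   sucrose_licks = sucrose, water_licks = total - sucrose,
                   spt_percent = 100 * sucrose / total,
                   tst_mobility_s = max(0, tst),
                   social_index = min(1, max(0, stats::rnorm(1, 0.65, 0.12))),
                   stringsAsFactors = FALSE)
      }))
    }))
  })
  seeds <- matrix(0L, nrow(mice), length(epochs),
                  dimnames = list(ids, epochs))
  for (i in seq_len(nrow(mice)))
    for (j in seq_along(epochs))
      seeds[i, j] <- deriveSeed(config@seed, ids[i], epochs[j], "session")
  new("SyntheticCohort", config = config, mice = mice, behavior = behavior,
      sessionSeeds = seeds)
}

## Per-mouse persistent cell identities and facial map, regenerated
## deterministically from the cohort seed.
mousePersistent <- function(cohort, mouseId) {
  withr::with_seed(deriveSeed(cohort@config@seed, mouseId, "cells"), {
    list(amplitudes = drawAmplitudes(cohort@config@nNeuronsPerMouse),
         faceMap = drawFaceMap())
  })
}

#' Materialize one session of a synthetic cohort
#'
#' @param cohort A [generateCohort()] result.
#' @param mouseId,epoch Which session to materialize.
#' @param withNeural,withKeypoints Toggle the heavy components.
#' @return See [generateSession()].
#' @rdname generateCohort
#' @export
cohortSession <- function(cohort, mouseId, epoch,
                          withNeural = TRUE, withKeypoints = TRUE) {
  stopifnot(is(cohort, "SyntheticCohort"))
  i <- match(mouseId, cohort@mice$mouse_id)
  if (is.na(i)) stopf("unknown mouse '%s'", mouseId)
  if (!epoch %in% cohort@config@epochs)
    stopf("epoch '%s' is not part of this cohort", epoch)
  cfg <- cohort@config
  pers <- mousePersistent(cohort, mouseId)
  generateSession(cfg@design, cfg@phenotypes[[cohort@mice$phenotype[i]]],
                  epoch, seed = cohort@sessionSeeds[mouseId, epoch],
                  nNeurons = cfg@nNeuronsPerMouse,
                  noiseSd = cfg@noiseSdNeural, tau = cfg@calciumDecayTau,
                  jitterSd = cfg@keypointJitterSd, mouseIdTag = mouseId,
                  amplitudes = pers$amplitudes, faceMap = pers$faceMap,
                  withNeural = withNeural, withKeypoints = withKeypoints)
}

#' ROI match table between two epochs of a synthetic cohort
#'
#' For each mouse, a deterministic subset of cells (the configured
#' `roiMatchFraction`) is reported as successfully tracked between the two
#' sessions, mirroring the output of cross-session cell registration.
#'
#' @param epochA,epochB Epoch tags.
#' @return Data frame with columns mouse_id, epoch_a, roi_a, epoch_b, roi_b;
#'   the mapping is one-to-one within each mouse.
#' @rdname generateCohort
#' @export
cohortRoiMatch <- function(cohort, epochA, epochB) {
  stopifnot(is(cohort, "SyntheticCohort"))
  cfg <- cohort@config
  do.call(rbind, lapply(cohort@mice$mouse_id, function(m) {
    idx <- withr::with_seed(
      deriveSeed(cfg@seed, m, "match", epochA, epochB),
      sort(sample(cfg@nNeuronsPerMouse,
                  max(1L, round(cfg@roiMatchFraction * cfg@nNeuronsPerMouse)))))
    data.frame(mouse_id = m, epoch_a = epochA,
               roi_a = paste0(m, "_", epochA, "_c", idx),
               epoch_b = epochB,
               roi_b = paste0(m, "_", epochB, "_c", idx),
               stringsAsFactors = FALSE)
  }))
}
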