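## Neural analyses: event alignment, neuron-count matching, leave-one-animal-
## out trajectory statistics, ROI-matched reward/punishment length ratios,
## and per-trial PC features for phenotype decoding.

NEURAL_EVENTS <- c("reward_CS", "punish_CS", "first_lick", "reward_US",
                   "punish_US")

## Resolve the alignment times of a task event within a session.
eventTimes <- function(trials, event, licks = NULL) {
  switch(event,
    reward_CS = trials$cs_onset_s[startsWith(trials$type, "reward")],
    punish_CS = trials$cs_onset_s[startsWith(trials$type, "punish")],
    reward_US = trials$us_onset_s[trials$type == "reward"],
    punish_US = trials$us_onset_s[trials$type == "punish"],
    first_lick = {
      if (is.null(licks))
        stopf("first_lick alignment needs the lick train")
      rw <- which(trials$type == "reward")
      ## search window: US availability up to the next trial's CS onset
      nextCs <- c(trials$cs_onset_s[-1], Inf)[rw]
      fl <- vapply(seq_along(rw), function(i) {
        u <- trials$us_onset_s[rw[i]]
        after <- licks[licks >= u & licks < nextCs[i]]
        if (length(after)) after[1] else NA_real_
      }, numeric(1))
      fl    # NA entries = reward trials with no lick, dropped by the caller
    },
    stopf("unknown event '%s' (use one of %s)", event,
          paste(NEURAL_EVENTS, collapse = ", ")))
}

#' Align a neural session to task events
#'
#' Cuts the activity matrix into a neurons x bins x trials tensor around
#' each occurrence of a task event, averaging frames into 100-ms (default)
#' bins. `first_lick` aligns to the first lick at or after US availability
#' on reward trials; reward trials with no lick are dropped and counted, as
#' are trials whose peri-event window leaves the recording.
#'
#' @param session A [neuralSession()].
#' @param trials The session's trial table.
#' @param event One of `"reward_CS"`, `"punish_CS"`, `"first_lick"`,
#'   `"reward_US"`, `"punish_US"`.
#' @param window `(start, end)` window around the event (s).
#' @param binWidth Bin width (s).
#' @param licks Lick timestamps, required for `first_lick`.
#' @return A raw [eventAlignedTensor()] (`zMode = "raw"`); dropped-trial
#'   count in its `nDropped` slot.
#' @export
alignEvents <- function(session, trials, event, window = c(-10, 10),
                        binWidth = 0.1, licks = NULL) {
  stopifnot(is(session, "NeuralSession"))
  times <- eventTimes(trials, event, licks)
  nDropped <- sum(is.na(times))
  times <- times[!is.na(times)]
  act <- activityMatrix(session)
  fr <- frameRate(session)
  tf <- (seq_len(ncol(act)) - 1L) / fr
  nb <- round(diff(window) / binWidth)
  keep <- times + window[1] >= 0 & times + window[2] <= tf[length(tf)] + 1 / fr
  nDropped <- nDropped + sum(!keep)
  times <- times[keep]
  if (!length(times))
    stopf("no resolvable '%s' events inside the recording", event)
  out <- array(NA_real_, c(nrow(act), nb, length(times)))
  for (k in seq_along(times)) {
    rel <- tf - times[k]
    ## epsilon guards keep frames lying exactly on bin boundaries in a
    ## consistent bin regardless of floating-point rounding
    idx <- which(rel >= window[1] - 1e-9 & rel < window[2] - 1e-9)
    bins <- pmin(nb, pmax(1L, floor((rel[idx] - window[1]) / binWidth +
                                      1e-9) + 1L))
    sums <- rowsum(t(act[, idx, drop = FALSE]), bins)
    cnt <- as.integer(table(bins))
    out[, , k] <- t(sums / cnt)
  }
  eventAlignedTensor(out, binWidth = binWidth, window = window,
                     event = event, zMode = "raw", nDropped = nDropped)
}

#' Match neuron counts across groups
#'
#' Uniform random subsample (without replacement) of each group's units down
#' to the smallest group size, so trajectory statistics compare populations
#' of equal dimensionality. Deterministic for a given seed.
#'
#' @param groups Named list of unit-identifier vectors.
#' @param seed Integer seed.
#' @return Named list of subsampled identifier vectors, all of equal length.
#' @export
matchNeuronCounts <- function(groups, seed = 1L) {
  if (!length(groups) || any(!lengths(groups)))
    stopf("every group must contain at least one unit")
  nMin <- min(lengths(groups))
  withr::with_seed(as.integer(seed), {
    lapply(groups, function(g) if (length(g) == nMin) g else sample(g, nMin))
  })
}

#' Leave-one-animal-out trajectory lengths
#'
#' Jackknife over mice: for each held-out mouse, the remaining mice's units
#' are stacked, projected through the SAME fixed PCA coefficients, and the
#' trajectory length of the group-mean response is measured. The number of
#' iterations equals the number of mice in the group.
#'
#' @param responses Named list (one entry per mouse) of units x bins mean
#'   z-scored response matrices.
#' @param rowsList Named list mapping each mouse's rows to row indices of
#'   the fitted model.
#' @param model A shared [fitPCA()] model.
#' @param nPcs Components used for quantification.
#' @param window Length quantification window (s), default post-event 0--10.
#' @param binWidth,alignWindow Bin grid of the responses.
#' @return Named numeric vector: one length per held-out mouse.
#' @export
looGroupLengths <- function(responses, rowsList, model, nPcs,
                            window = c(0, 10), binWidth = 0.1,
                            alignWindow = c(-10, 10)) {
  mice <- names(responses)
  if (length(mice) < 2L)
    stopf("leave-one-out needs at least 2 mice in the group")
  if (!identical(sort(mice), sort(names(rowsList))))
    stopf("responses and rowsList must name the same mice")
  out <- stats::setNames(numeric(length(mice)), mice)
  for (m in mice) {
    keep <- setdiff(mice, m)
    resp <- do.call(rbind, responses[keep])
    rows <- unlist(rowsList[keep], use.names = FALSE)
    traj <- projectTrajectory(model, resp, nPcs, binWidth = binWidth,
                              window = alignWindow,
                              label = paste0("loo_-", m), rows = rows)
    out[m] <- trajectoryLength(traj, window)
  }
  out
}

## Match the ROI table of one mouse to row indices of its two sessions.
matchedRows <- function(roiMatch, mouse, sessionA, sessionB) {
  mm <- roiMatch[roiMatch$mouse_id == mouse, , drop = FALSE]
  ia <- match(mm$roi_a, roiIds(sessionA))
  ib <- match(mm$roi_b, roiIds(sessionB))
  ok <- !is.na(ia) & !is.na(ib)
  if (!any(ok)) stopf("no matched cells for mouse '%s'", mouse)
  if (anyDuplicated(ia[ok]) || anyDuplicated(ib[ok]))
    stopf("ROI match table is not one-to-one for mouse '%s'", mouse)
  list(a = ia[ok], b = ib[ok])
}

#' ROI-matched reward/punishment trajectory-length ratio
#'
#' For each mouse, the cells tracked across a pair of time points are
#' super-global z-scored across the two sessions, aligned to the reward and
#' punishment US, and projected into a PC space fit once on the pooled
#' matched population (same coefficients for both epochs and all mice).
#' The post-event (0--10 s) trajectory length on reward trials divided by
#' the length on punishment trials gives the per-epoch reward/punishment
#' ratio; the normalized change is ratio at the second epoch over ratio at
#' the first, so values above 1 mean reward processing gained relative to
#' punishment between the two time points.
#'
#' @param sessionsA,sessionsB Named lists (by mouse) of [neuralSession()]
#'   objects at the two epochs.
#' @param trialsA,trialsB Named lists of the matching trial tables.
#' @param roiMatch ROI match table (mouse_id, epoch_a, roi_a, epoch_b,
#'   roi_b), one-to-one per mouse.
#' @param window Length quantification window (s).
#' @param alignWindow,binWidth Peri-event grid.
#' @param varianceFraction PC count chosen as the smallest capturing this
#'   variance fraction (default 0.60); overridden by `nPcs`.
#' @param nPcs Optional fixed component count.
#' @return Data frame with one row per mouse: `ratio_a`, `ratio_b`,
#'   `normalized_change`, and the matched-cell count.
#' @export
rewardPunishmentRatio <- function(sessionsA, sessionsB, trialsA, trialsB,
                                  roiMatch, window = c(0, 10),
                                  alignWindow = c(-10, 10), binWidth = 0.1,
                                  varianceFraction = 0.6, nPcs = NULL) {
  mice <- names(sessionsA)
  stopifnot(identical(mice, names(sessionsB)))
  resp <- list(); rowsOf <- list(); offset <- 0L
  nCells <- stats::setNames(integer(length(mice)), mice)
  for (m in mice) {
    rows <- matchedRows(roiMatch, m, sessionsA[[m]], sessionsB[[m]])
    subA <- sessionsA[[m]][rows$a, ]
    subB <- sessionsB[[m]][rows$b, ]
    zs <- superGlobalZscore(list(neuralSession(activityMatrix(subA),
                                               frameRate(sessionsA[[m]]),
                                               roiIds(subA), m, "a"),
                                 neuralSession(activityMatrix(subB),
                                               frameRate(sessionsB[[m]]),
                                               roiIds(subB), m, "b")))
    mk <- function(sess, trials, event)
      trialMean(alignEvents(sess, trials, event, window = alignWindow,
                            binWidth = binWidth))
    resp[[m]] <- list(RA = mk(zs[[1]], trialsA[[m]], "reward_US"),
                      PA = mk(zs[[1]], trialsA[[m]], "punish_US"),
                      RB = mk(zs[[2]], trialsB[[m]], "reward_US"),
                      PB = mk(zs[[2]], trialsB[[m]], "punish_US"))
    nCells[m] <- length(rows$a)
    rowsOf[[m]] <- offset + seq_len(nCells[m])
    offset <- offset + nCells[m]
  }
  pooled <- do.call(rbind, lapply(resp, function(r)
    cbind(r$RA, r$PA, r$RB, r$PB)))
  model <- fitPCA(pooled)
  if (is.null(nPcs)) nPcs <- pcsForVariance(model, varianceFraction)
  lenOf <- function(m, what) {
    traj <- projectTrajectory(model, resp[[m]][[what]], nPcs,
                              binWidth = binWidth, window = alignWindow,
                              label = paste(m, what), rows = rowsOf[[m]])
    trajectoryLength(traj, window)
  }
  out <- do.call(rbind, lapply(mice, function(m) {
    lr <- c(lenOf(m, "RA"), lenOf(m, "RB"))
    lp <- c(lenOf(m, "PA"), lenOf(m, "PB"))
    if (any(lp == 0))
      stopf("undefined ratio: punishment trajectory length is zero for '%s'", m)
    data.frame(mouse_id = m, n_matched = nCells[[m]],
               ratio_a = lr[1] / lp[1], ratio_b = lr[2] / lp[2],
               normalized_change = (lr[2] / lp[2]) / (lr[1] / lp[1]),
               stringsAsFactors = FALSE)
  }))
  attr(out, "nPcs") <- nPcs
  rownames(out) <- NULL
  out
}

#' Per-trial PC features for phenotype decoding
#'
#' Builds the decoder inputs from a set of sessions: each mouse's session is
#' aligned to the requested event and locally z-scored; a single PCA is fit
#' on the stacked trial-mean responses (units from all mice, time bins as
#' columns); every individual trial is then projected through that mouse's
#' loading rows, yielding per-trial, per-bin PC coordinates.
#'
#' @param sessions Named list (by mouse) of [neuralSession()] objects.
#' @param trialsList Named list of trial tables.
#' @param labels Named character/factor: phenotype per mouse.
#' @param event Alignment event (see [alignEvents()]).
#' @param licksList Optional named list of lick trains (for `first_lick`).
#' @param nPcs Components kept as features (default 8).
#' @param window,binWidth Peri-event grid (the PCA is fit on this full
#'   window).
#' @param baselineWindow Local z-score baseline.
#' @param featureWindow Optional sub-window (s); only its bins are returned
#'   as decoder features (default: the full window).
#' @return List with `features` (samples x PCs x bins array), `labels`
#'   (factor, one per trial sample), `mouse` (sample origin), and `model`.
#' @export
neuralTrialFeatures <- function(sessions, trialsList, labels, event,
                                licksList = NULL, nPcs = 8L,
                                window = c(-10, 10), binWidth = 0.1,
                                baselineWindow = c(-10, 0),
                                featureWindow = NULL) {
  mice <- names(sessions)
  tensors <- lapply(mice, function(m)
    localZscore(alignEvents(sessions[[m]], trialsList[[m]], event,
                            window = window, binWidth = binWidth,
                            licks = licksList[[m]]), baselineWindow))
  names(tensors) <- mice
  means <- lapply(tensors, trialMean)
  pooled <- do.call(rbind, means)
  model <- fitPCA(pooled)
  nPcs <- min(nPcs, ncol(model@loadings))
  nUnits <- vapply(means, nrow, integer(1))
  offsets <- cumsum(c(0L, nUnits[-length(nUnits)]))
  names(offsets) <- mice
  keepBins <- if (is.null(featureWindow)) seq_len(dim(tensors[[1]]@data)[2])
              else binsInWindow(tensors[[1]], featureWindow)
  nb <- length(keepBins)
  featList <- list(); labVec <- character(); mouseVec <- character()
  for (m in mice) {
    d <- tensors[[m]]@data
    rows <- offsets[[m]] + seq_len(dim(d)[1])
    W <- model@loadings[rows, seq_len(nPcs), drop = FALSE]
    ctr <- model@center[rows]
    for (tr in seq_len(dim(d)[3])) {
      pcByBin <- t(W) %*% (d[, , tr] - ctr)   # pcs x bins (full window)
      featList[[length(featList) + 1L]] <- pcByBin[, keepBins, drop = FALSE]
      labVec <- c(labVec, as.character(labels[[m]]))
      mouseVec <- c(mouseVec, m)
    }
  }
  features <- array(NA_real_, c(length(featList), nPcs, nb))
  for (i in seq_along(featList)) features[i, , ] <- featList[[i]]
  binTimes <- (window[1] + (keepBins - 0.5) * binWidth)
  list(features = features, labels = factor(labVec), mouse = mouseVec,
       model = model, binTimes = binTimes)
}
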