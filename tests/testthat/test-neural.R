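## Build a session with an impulse-plus-decay response at a fixed latency
## after every US of the requested type; analytic ground truth for
## alignment tests.
impulseSession <- function(trials, frameRate = 20, latency = 0, amp = 10,
                           type = "reward", nNeurons = 3, base = 0) {
  dur <- max(trials$cs_onset_s) + 20
  nF <- ceiling(dur * frameRate)
  act <- matrix(base, nNeurons, nF)
  ev <- trials$us_onset_s[trials$type == type] + latency
  for (t0 in ev) {
    f <- floor(t0 * frameRate) + 1
    idx <- f:min(nF, f + 40)
    act[, idx] <- act[, idx] +
      amp * exp(-(seq_along(idx) - 1) / (frameRate * 0.3))
  }
  neuralSession(act, frameRate = frameRate)
}

mkTrials <- function(n, type = "reward", spacing = 30, first = 15) {
  data.frame(trial_index = seq_len(n), type = type,
             cs_onset_s = first + (seq_len(n) - 1) * spacing,
             us_onset_s = first + (seq_len(n) - 1) * spacing + 2,
             tone_khz = 9)
}

test_that("event alignment lands responses in the correct bin", {
  tr <- mkTrials(5)
  s <- impulseSession(tr, latency = 0)
  ten <- alignEvents(s, tr, "reward_US")
  mu <- trialMean(ten)
  peakBin <- which.max(colMeans(mu))
  expect_equal(binCenters(ten)[peakBin], 0.05)   # first bin after the event
  ## known 0.5-s latency lands in the bin containing t = 0.5
  s2 <- impulseSession(tr, latency = 0.5)
  ten2 <- alignEvents(s2, tr, "reward_US")
  peak2 <- which.max(colMeans(trialMean(ten2)))
  expect_equal(binCenters(ten2)[peak2], 0.55)
  ## per-trial argmax is stable across trials
  for (k in seq_len(dim(tensorData(ten2))[3]))
    expect_equal(binCenters(ten2)[which.max(tensorData(ten2)[1, , k])], 0.55)
})

test_that("constant activity aligns to a flat tensor and trials drop cleanly", {
  tr <- mkTrials(4)
  s <- neuralSession(matrix(2.5, 2, ceiling(20 * (max(tr$cs_onset_s) + 20))),
                     frameRate = 20)
  ten <- alignEvents(s, tr, "reward_US")
  expect_true(all(abs(tensorData(ten) - 2.5) < 1e-12))
  ## a trial whose window exceeds the recording is dropped and counted
  trLate <- mkTrials(4, first = 5)   # first window starts before t = 0
  tenLate <- alignEvents(s, trLate, "reward_US")
  expect_identical(tenLate@nDropped, 1L)
  expect_identical(dim(tensorData(tenLate))[3], 3L)
  expect_error(alignEvents(s, mkTrials(3, type = "punish"), "reward_US"),
               "no resolvable")
})

test_that("first-lick alignment drops lick-free trials with a count", {
  tr <- mkTrials(4)
  s <- impulseSession(tr)
  licks <- c(tr$us_onset_s[1] + 0.2, tr$us_onset_s[3] + 0.4)
  ten <- alignEvents(s, tr, "first_lick", licks = licks)
  expect_identical(dim(tensorData(ten))[3], 2L)
  expect_identical(ten@nDropped, 2L)
  expect_error(alignEvents(s, tr, "first_lick"), "lick train")
})

test_that("neuron-count matching subsamples to the minimum group size", {
  g <- list(a = paste0("a", 1:10), b = paste0("b", 1:7), c = paste0("c", 1:12))
  m <- matchNeuronCounts(g, seed = 2)
  expect_identical(unname(lengths(m)), c(7L, 7L, 7L))
  expect_identical(m$b, g$b)
  expect_true(all(m$a %in% g$a))
  expect_identical(matchNeuronCounts(g, seed = 2), m)
  eq <- list(a = 1:5, b = 6:10)
  expect_identical(matchNeuronCounts(eq, seed = 1), eq)
  expect_error(matchNeuronCounts(list(a = 1:3, b = integer())), "at least one")
})

test_that("leave-one-animal-out has one iteration per mouse", {
  set.seed(10)
  resp <- lapply(c(m1 = 1, m2 = 2, m3 = 3), function(i)
    matrix(rnorm(4 * 200), 4))
  pooled <- do.call(rbind, resp)
  model <- fitPCA(pooled)
  rows <- list(m1 = 1:4, m2 = 5:8, m3 = 9:12)
  lens <- looGroupLengths(resp, rows, model, nPcs = 3)
  expect_identical(names(lens), c("m1", "m2", "m3"))
  expect_true(all(lens > 0))
  ## cloned mice: every iteration leaves out an identical animal
  respC <- list(m1 = resp$m1, m2 = resp$m1, m3 = resp$m1)
  pooledC <- do.call(rbind, respC)
  modelC <- fitPCA(pooledC)
  lensC <- looGroupLengths(respC, rows, modelC, nPcs = 3)
  expect_equal(max(lensC) - min(lensC), 0, tolerance = 1e-10)
  expect_error(looGroupLengths(resp["m1"], rows["m1"], model, 2),
               "at least 2 mice")
})

## Two-epoch, two-mouse fixture for the ratio analysis, built from
## deterministic kernel responses (no noise).
ratioFixture <- function(rewardAmpB = 2, punishAmpB = 2, scale = 1,
                         samePattern = FALSE) {
  frameRate <- 20
  mkSess <- function(rAmp, pAmp, epoch, mouse) {
    tr <- rbind(mkTrials(4, "reward", first = 15),
                mkTrials(4, "punish", first = 135))
    tr$trial_index <- seq_len(nrow(tr))
    dur <- max(tr$cs_onset_s) + 20
    nF <- ceiling(dur * frameRate)
    act <- matrix(0, 4, nF)
    addEv <- function(times, amps) {
      for (t0 in times) {
        f <- floor(t0 * frameRate) + 1
        idx <- f:min(nF, f + 60)
        for (n in 1:4)
          act[n, idx] <<- act[n, idx] +
            amps[n] * exp(-(seq_along(idx) - 1) / (frameRate * 0.4))
      }
    }
    addEv(tr$us_onset_s[tr$type == "reward"], rAmp * c(1, 2, 0.5, 1.5))
    addEv(tr$us_onset_s[tr$type == "punish"],
          pAmp * (if (samePattern) c(1, 2, 0.5, 1.5) else c(1.5, 0.5, 2, 1)))
    list(session = neuralSession(scale * act, frameRate,
                                 roiIds = paste0(mouse, "_", epoch, "_c", 1:4),
                                 mouseId = mouse, epoch = epoch),
         trials = tr)
  }
  mice <- c("m1", "m2")
  a <- lapply(mice, function(m) mkSess(2, 2, "baseline", m))
  b <- lapply(mice, function(m) mkSess(rewardAmpB, punishAmpB, "stress_w6", m))
  names(a) <- names(b) <- mice
  roiMatch <- do.call(rbind, lapply(mice, function(m)
    data.frame(mouse_id = m, epoch_a = "baseline",
               roi_a = paste0(m, "_baseline_c", 1:4),
               epoch_b = "stress_w6",
               roi_b = paste0(m, "_stress_w6_c", 1:4))))
  list(sessionsA = lapply(a, `[[`, "session"),
       sessionsB = lapply(b, `[[`, "session"),
       trialsA = lapply(a, `[[`, "trials"),
       trialsB = lapply(b, `[[`, "trials"),
       roiMatch = roiMatch)
}

test_that("identical reward and punishment dynamics give unit-change ratios", {
  fx <- ratioFixture(rewardAmpB = 2, punishAmpB = 2)
  tab <- rewardPunishmentRatio(fx$sessionsA, fx$sessionsB, fx$trialsA,
                               fx$trialsB, fx$roiMatch)
  expect_equal(tab$normalized_change, rep(1, 2), tolerance = 1e-6)
  ## identical response patterns for both valences: per-epoch ratio is 1
  fxS <- ratioFixture(rewardAmpB = 2, punishAmpB = 2, samePattern = TRUE)
  tabS <- rewardPunishmentRatio(fxS$sessionsA, fxS$sessionsB, fxS$trialsA,
                                fxS$trialsB, fxS$roiMatch)
  expect_equal(tabS$ratio_a, rep(1, 2), tolerance = 1e-6)
  expect_equal(tabS$ratio_b, rep(1, 2), tolerance = 1e-6)
})

test_that("a planted reward gain raises the normalized ratio change", {
  fx <- ratioFixture(rewardAmpB = 4, punishAmpB = 2)
  tab <- rewardPunishmentRatio(fx$sessionsA, fx$sessionsB, fx$trialsA,
                               fx$trialsB, fx$roiMatch)
  expect_true(all(tab$normalized_change > 1.2))
})

test_that("the ratio is invariant to common activity rescaling", {
  fx1 <- ratioFixture(rewardAmpB = 3, punishAmpB = 2, scale = 1)
  fx2 <- ratioFixture(rewardAmpB = 3, punishAmpB = 2, scale = 17)
  t1 <- rewardPunishmentRatio(fx1$sessionsA, fx1$sessionsB, fx1$trialsA,
                              fx1$trialsB, fx1$roiMatch)
  t2 <- rewardPunishmentRatio(fx2$sessionsA, fx2$sessionsB, fx2$trialsA,
                              fx2$trialsB, fx2$roiMatch)
  expect_equal(t1$ratio_a, t2$ratio_a, tolerance = 1e-8)
  expect_equal(t1$normalized_change, t2$normalized_change, tolerance = 1e-8)
})

test_that("ROI matching composes with its inverse to the identity", {
  co <- generateCohort(cohortConfig(nControl = 2, nResilient = 2,
                                    nSusceptible = 2, nNeuronsPerMouse = 15,
                                    epochs = c("baseline", "stress_w6"),
                                    seed = 6))
  fwd <- cohortRoiMatch(co, "baseline", "stress_w6")
  back <- stats::setNames(fwd$roi_a, fwd$roi_b)
  expect_identical(unname(back[fwd$roi_b]), fwd$roi_a)
  expect_false(anyDuplicated(fwd$roi_a) > 0)
})

test_that("null planted effects center the ratio change at one", {
  d <- tinyDesign()
  ph <- flatPhenotype()
  changes <- unlist(lapply(1:10, function(seed) {
    mice <- paste0("m", 1:2)
    mk <- function(m, ep, s) {
      amp <- withr::with_seed(deriveSeed(seed, m),
                              drawAmplitudes(20))
      generateSession(d, ph, ep, seed = s, nNeurons = 20, amplitudes = amp,
                      mouseIdTag = m, withKeypoints = FALSE)
    }
    a <- lapply(mice, function(m) mk(m, "baseline", deriveSeed(seed, m, "a")))
    b <- lapply(mice, function(m) mk(m, "stress_w6", deriveSeed(seed, m, "b")))
    names(a) <- names(b) <- mice
    roiMatch <- do.call(rbind, lapply(mice, function(m)
      data.frame(mouse_id = m, epoch_a = "baseline",
                 roi_a = paste0(m, "_baseline_c", 1:20),
                 epoch_b = "stress_w6",
                 roi_b = paste0(m, "_stress_w6_c", 1:20))))
    rewardPunishmentRatio(lapply(a, `[[`, "neural"),
                          lapply(b, `[[`, "neural"),
                          lapply(a, `[[`, "trials"),
                          lapply(b, `[[`, "trials"),
                          roiMatch)$normalized_change
  }))
  expect_lt(abs(mean(changes) - 1), 0.1)
})

test_that("per-trial PC features carry mouse labels and bin structure", {
  d <- tinyDesign()
  sess <- lapply(c(m1 = 11, m2 = 12), function(s)
    generateSession(d, flatPhenotype(), "baseline", seed = s, nNeurons = 12,
                    mouseIdTag = paste0("m", s - 10), withKeypoints = FALSE))
  feat <- neuralTrialFeatures(
    sessions = lapply(sess, `[[`, "neural"),
    trialsList = lapply(sess, `[[`, "trials"),
    labels = c(m1 = "control", m2 = "susceptible"), event = "reward_US",
    nPcs = 4, featureWindow = c(0, 5))
  expect_identical(dim(feat$features)[2:3], c(4L, 50L))
  expect_identical(length(feat$labels), dim(feat$features)[1])
  expect_identical(sum(feat$mouse == "m1"), 8L)   # reward trials of m1
  expect_equal(range(feat$binTimes), c(0.05, 4.95))
})
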