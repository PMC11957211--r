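test_that("generation is byte-identical under a fixed seed", {
  d <- tinyDesign()
  ph <- flatPhenotype()
  s1 <- generateSession(d, ph, "baseline", seed = 1, nNeurons = 10)
  s2 <- generateSession(d, ph, "baseline", seed = 1, nNeurons = 10)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$licks, s2$licks)
  expect_identical(activityMatrix(s1$neural), activityMatrix(s2$neural))
  expect_identical(s1$keypoints@coords, s2$keypoints@coords)
  co1 <- generateCohort(cohortConfig(nControl = 2, nResilient = 2,
                                     nSusceptible = 2, seed = 3))
  co2 <- generateCohort(cohortConfig(nControl = 2, nResilient = 2,
                                     nSusceptible = 2, seed = 3))
  expect_identical(cohortBehavior(co1), cohortBehavior(co2))
  expect_identical(co1@sessionSeeds, co2@sessionSeeds)
})

test_that("a cohort defines one session per mouse per epoch", {
  co <- generateCohort(cohortConfig(nControl = 2, nResilient = 2,
                                    nSusceptible = 2, seed = 1))
  expect_identical(nSessions(co), 60L)   # 6 mice x 10 epochs
  expect_identical(nrow(cohortBehavior(co)), 60L)
})

test_that("ground-truth labels are recorded separately from derived ones", {
  co <- generateCohort(cohortConfig(nControl = 2, nResilient = 2,
                                    nSusceptible = 2, seed = 2))
  expect_setequal(unique(cohortMice(co)$phenotype),
                  c("control", "resilient", "susceptible"))
  expect_false("phenotype" %in% names(cohortBehavior(co)))
})

test_that("post-stress SPT group means follow the planted ordering", {
  co <- generateCohort(cohortConfig(nControl = 8, nResilient = 8,
                                    nSusceptible = 8,
                                    epochs = c("baseline", "stress_w6"),
                                    seed = 4))
  b <- cohortBehavior(co)
  b <- b[b$epoch == "stress_w6", ]
  mice <- cohortMice(co)
  gm <- tapply(b$spt_percent, mice$phenotype[match(b$mouse_id, mice$mouse_id)],
               mean)
  expect_lt(gm[["susceptible"]], gm[["control"]])
  expect_lt(gm[["susceptible"]], gm[["resilient"]])
  expect_lt(abs(gm[["control"]] - gm[["resilient"]]), 6)
})

test_that("trial ordering satisfies every pseudorandomization constraint", {
  d <- sessionDesign()
  ph <- flatPhenotype()
  for (seed in 1:8) {
    tr <- generateSession(d, ph, "baseline", seed = seed, nNeurons = 2,
                          withNeural = FALSE, withKeypoints = FALSE)$trials
    expect_identical(tr$type[1:3], rep("reward", 3))
    pun <- tr$type %in% c("punish", "punish_catch")
    runs <- rle(pun)
    expect_true(all(runs$lengths[runs$values] < 3))
    catchPos <- which(tr$type %in% c("reward_catch", "punish_catch"))
    expect_true(all(catchPos > floor(0.85 * nrow(tr))))
    expect_true(all(diff(tr$cs_onset_s) > 0))
    withUs <- !is.na(tr$us_onset_s)
    expect_equal(tr$us_onset_s[withUs], tr$cs_onset_s[withUs] + 2)
  }
})

test_that("infeasible constraint sets raise a generation error", {
  bad <- sessionDesign(nReward = 3, nRewardCatch = 4, nPunish = 1,
                       nPunishCatch = 4)   # 8 catch into a 12-trial tail of 1
  expect_error(generateSession(bad, flatPhenotype(), "baseline", seed = 1,
                               withNeural = FALSE, withKeypoints = FALSE),
               "infeasible")
})

test_that("zero gains and zero noise give an identically zero matrix", {
  s <- generateSession(tinyDesign(), flatPhenotype(0, 0), "baseline",
                       seed = 1, nNeurons = 5, noiseSd = 0,
                       withKeypoints = FALSE)
  expect_true(all(activityMatrix(s$neural) == 0))
})

test_that("licks occupy the planted anticipatory and consummatory windows", {
  d <- tinyDesign()
  s <- generateSession(d, flatPhenotype(antic = 8, cons = 8), "baseline",
                       seed = 6, withNeural = FALSE, withKeypoints = FALSE)
  tr <- s$trials
  inWindow <- vapply(s$licks, function(t) {
    any(startsWith(tr$type, "reward") & t >= tr$cs_onset_s &
          t <= tr$cs_onset_s + d@csDuration + 3)
  }, logical(1))
  expect_true(all(inWindow))
  pun <- tr[tr$type == "punish", ]
  near <- vapply(s$licks, function(t)
    any(t >= pun$cs_onset_s & t < pun$cs_onset_s + 5), logical(1))
  expect_false(any(near))
})

test_that("cross-session cell identity is deterministic and one-to-one", {
  co <- generateCohort(cohortConfig(nControl = 2, nResilient = 2,
                                    nSusceptible = 2, nNeuronsPerMouse = 20,
                                    roiMatchFraction = 0.6,
                                    epochs = c("baseline", "stress_w6"),
                                    seed = 5))
  rm1 <- cohortRoiMatch(co, "baseline", "stress_w6")
  rm2 <- cohortRoiMatch(co, "baseline", "stress_w6")
  expect_identical(rm1, rm2)
  for (m in unique(rm1$mouse_id)) {
    mm <- rm1[rm1$mouse_id == m, ]
    expect_identical(nrow(mm), 12L)   # 0.6 x 20
    expect_false(anyDuplicated(mm$roi_a) > 0)
    expect_false(anyDuplicated(mm$roi_b) > 0)
  }
  ## matched ids resolve in the materialized sessions
  s <- cohortSession(co, "m01", "baseline", withKeypoints = FALSE)
  expect_true(all(rm1$roi_a[rm1$mouse_id == "m01"] %in% roiIds(s$neural)))
})

test_that("invalid configurations name the offending field", {
  expect_error(cohortConfig(nControl = 0), "nControl")
  expect_error(cohortConfig(roiMatchFraction = 1.5), "roiMatchFraction")
  expect_error(cohortConfig(calciumDecayTau = -1), "calciumDecayTau")
  expect_error(sessionDesign(nReward = 2), "nReward")
  expect_error(sessionDesign(itiRange = c(30, 25)), "itiRange")
})

test_that("keypoint jitter degrades facial decoding monotonically", {
  d <- tinyDesign()
  sessionFeatures <- function(seed, amp, jitter) {
    out <- generateSession(d, flatPhenotype(facialAmp = amp), "baseline",
                           seed = seed, jitterSd = jitter, withNeural = FALSE)
    list(features = extractFacialFeatures(
           calibrateTrack(smoothTrack(out$keypoints), 100, 1)),
         trials = out$trials)
  }
  aucAt <- function(jitter, seed) {
    sess <- list(c1 = sessionFeatures(seed * 7 + 1, 1, jitter),
                 c2 = sessionFeatures(seed * 7 + 2, 1, jitter),
                 s1 = sessionFeatures(seed * 7 + 3, 2, jitter),
                 s2 = sessionFeatures(seed * 7 + 4, 2, jitter))
    feat <- facialTrialFeatures(
      lapply(sess, `[[`, "features"), lapply(sess, `[[`, "trials"),
      labels = c(c1 = "control", c2 = "control",
                 s1 = "susceptible", s2 = "susceptible"),
      nPcs = 4, window = c(-5, 5), binWidth = 0.5)
    res <- decodeTimecourse(feat$features, feat$labels, nPcs = 4,
                            nFolds = 4, seed = seed)
    mean(meanAuc(res), na.rm = TRUE)
  }
  levels <- c(0.5, 5, 25)
  means <- vapply(levels, function(j)
    mean(vapply(1:20, function(s) aucAt(j, s), numeric(1))), numeric(1))
  expect_true(all(diff(means) < 0))
})
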