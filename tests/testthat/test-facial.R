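## Build a track directly from a frames x nodes x 2 coordinate array
## (confidence 1 everywhere unless given).
mkTrack <- function(xy, fps = 30, conf = 1) {
  co <- array(NA_real_, c(dim(xy)[1], dim(xy)[2], 3))
  co[, , 1:2] <- xy
  co[, , 3] <- conf
  keypointTrack(co, nodes = facialSkeleton()@nodes[seq_len(dim(xy)[2])],
                fps = fps)
}

restArray <- function(nFrames) {
  rest <- restFacePose()
  xy <- array(NA_real_, c(nFrames, 13, 2))
  xy[, , 1] <- outer(rep(1, nFrames), rest[, 1])
  xy[, , 2] <- outer(rep(1, nFrames), rest[, 2])
  xy
}

test_that("Savitzky-Golay smoothing preserves constants and linear ramps", {
  xy <- restArray(50)
  tr <- mkTrack(xy)
  sm <- smoothTrack(tr)
  expect_equal(sm@coords[, , 1:2], xy, tolerance = 1e-9)
  ramp <- xy
  ramp[, 1, 1] <- xy[, 1, 1] + seq(0, 10, length.out = 50)
  smR <- smoothTrack(mkTrack(ramp))
  expect_equal(smR@coords[, 1, 1], ramp[, 1, 1], tolerance = 1e-9)
  expect_error(smoothTrack(mkTrack(restArray(4))), "shorter")
  expect_error(smoothTrack(tr, windowFrames = 4), "odd")
  expect_error(smoothTrack(tr, windowFrames = 5, polyorder = 5), "smaller")
})

test_that("smoothing reduces residual noise around a known trajectory", {
  wins <- 0
  for (seed in 1:20) {
    set.seed(seed)
    clean <- sin(seq(0, 6 * pi, length.out = 200)) * 10
    xy <- restArray(200)
    noisy <- clean + rnorm(200, 0, 2)
    xy[, 1, 1] <- xy[, 1, 1] + noisy
    sm <- smoothTrack(mkTrack(xy))
    resIn <- var(noisy - clean)
    resOut <- var(sm@coords[, 1, 1] - (restFacePose()[1, 1] + clean))
    if (resOut < resIn) wins <- wins + 1
  }
  expect_equal(wins, 20)
})

test_that("low-confidence keypoints are interpolated before smoothing", {
  xy <- restArray(40)
  xy[, 1, 1] <- seq(0, 39)          # linear truth
  conf <- matrix(1, 40, 13)
  conf[20, 1] <- 0.1                # one dropout on a linear segment
  co <- array(NA_real_, c(40, 13, 3))
  co[, , 1:2] <- xy
  co[20, 1, 1] <- 500               # corrupted coordinate
  co[, , 3] <- conf
  sm <- smoothTrack(keypointTrack(co, fps = 30))
  expect_equal(sm@coords[20, 1, 1], 19, tolerance = 1e-9)
})

test_that("spout calibration sets px/cm and scales features homogeneously", {
  tr <- mkTrack(restArray(30))
  cal <- calibrateTrack(tr, 100, 1)
  expect_equal(cal@pxPerCm, 100)
  expect_error(calibrateTrack(tr, -5, 1), "> 0")
  f1 <- extractFacialFeatures(calibrateTrack(tr, 100, 1))
  f2 <- extractFacialFeatures(calibrateTrack(tr, 50, 1))
  d1 <- featureValues(f1)[channelInfo(f1)$kind == "distance", 1]
  d2 <- featureValues(f2)[channelInfo(f2)$kind == "distance", 1]
  expect_equal(d2, 2 * d1, tolerance = 1e-10)
  a1 <- featureValues(f1)[channelInfo(f1)$kind == "angle", 1]
  a2 <- featureValues(f2)[channelInfo(f2)$kind == "angle", 1]
  expect_equal(a1, a2, tolerance = 1e-10)   # angles are calibration-free
  ## cm -> px -> cm round trip
  px <- 50
  expect_equal(px / cal@pxPerCm * cal@pxPerCm, px)
})

test_that("the default registry yields 91 channels with stable metadata", {
  f <- extractFacialFeatures(calibrateTrack(mkTrack(restArray(10)), 80, 1))
  info <- channelInfo(f)
  expect_identical(nrow(featureValues(f)), 91L)
  expect_identical(as.vector(table(info$kind)[c("distance", "angle",
                                                "velocity", "acceleration",
                                                "area")]),
                   c(78L, 6L, 2L, 2L, 3L))
  f2 <- extractFacialFeatures(calibrateTrack(mkTrack(restArray(25)), 80, 1))
  expect_identical(info$name, channelInfo(f2)$name)
  expect_identical(info$units, channelInfo(f2)$units)
  expect_error(extractFacialFeatures(mkTrack(restArray(10))), "calibrated")
})

test_that("angles, areas and kinematics match textbook geometry", {
  xy <- restArray(10)
  ## collinear triple: nostril_left, nose_tip, nostril_right on one line
  xy[, 9, ] <- rep(c(0, 0), each = 10)
  xy[, 8, ] <- rep(c(1, 1), each = 10)    # nose_tip is the vertex
  xy[, 10, ] <- rep(c(2, 2), each = 10)
  f <- extractFacialFeatures(calibrateTrack(mkTrack(xy), 1, 1))
  expect_equal(unname(featureValues(f)["angle_nostril_flare", ]),
               rep(180, 10), tolerance = 1e-7)
  ## unit right triangle at 1 px/cm: area 0.5
  xy2 <- restArray(10)
  xy2[, 11, ] <- rep(c(0, 0), each = 10)  # mouth_upper
  xy2[, 12, ] <- rep(c(1, 0), each = 10)  # mouth_lower
  xy2[, 13, ] <- rep(c(0, 1), each = 10)  # chin
  f2 <- extractFacialFeatures(calibrateTrack(mkTrack(xy2), 1, 1))
  expect_equal(unname(featureValues(f2)["area_mouth", ]), rep(0.5, 10))
  ## constant 3 px/frame at 30 fps and 100 px/cm: 0.9 cm/s, 0 cm/s^2
  xy3 <- restArray(30)
  xy3[, 8, 1] <- xy3[, 8, 1] + 3 * (0:29)
  f3 <- extractFacialFeatures(calibrateTrack(mkTrack(xy3), 100, 1))
  expect_equal(unname(featureValues(f3)["speed_nose_tip", ]), rep(0.9, 30),
               tolerance = 1e-10)
  expect_equal(unname(featureValues(f3)["accel_nose_tip", ]), rep(0, 30),
               tolerance = 1e-10)
})

test_that("distances and areas are rigid-motion invariant", {
  set.seed(13)
  xy <- restArray(15)
  xy[, , 1] <- xy[, , 1] + rnorm(15 * 13, 0, 3)
  xy[, , 2] <- xy[, , 2] + rnorm(15 * 13, 0, 3)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  xyR <- xy
  for (f in 1:15) {
    rot <- cbind(xy[f, , 1], xy[f, , 2]) %*% R
    xyR[f, , 1] <- rot[, 1] + 40
    xyR[f, , 2] <- rot[, 2] - 17
  }
  fa <- extractFacialFeatures(calibrateTrack(mkTrack(xy), 50, 1))
  fb <- extractFacialFeatures(calibrateTrack(mkTrack(xyR), 50, 1))
  rigid <- channelInfo(fa)$kind %in% c("distance", "angle", "area")
  expect_equal(featureValues(fa)[rigid, ], featureValues(fb)[rigid, ],
               tolerance = 1e-8)
  ## kinematics are invariant under pure translation
  xyT <- xy
  xyT[, , 1] <- xy[, , 1] + 123
  fc <- extractFacialFeatures(calibrateTrack(mkTrack(xyT), 50, 1))
  kin <- channelInfo(fa)$kind %in% c("velocity", "acceleration")
  expect_equal(featureValues(fa)[kin, ], featureValues(fc)[kin, ],
               tolerance = 1e-8)
})

## Facial sessions for trajectory-level tests: short design, planted
## event-locked displacement via the generator.
facialSessions <- function(seeds, amp = 1, jitter = 1) {
  d <- tinyDesign()
  lapply(seeds, function(s) {
    out <- generateSession(d, flatPhenotype(facialAmp = amp), "baseline",
                           seed = s, jitterSd = jitter, withNeural = FALSE)
    feats <- extractFacialFeatures(
      calibrateTrack(smoothTrack(out$keypoints), 100, 1))
    list(features = feats, trials = out$trials)
  })
}

test_that("facial difference score detects post-event dynamics", {
  sess <- facialSessions(c(s1 = 31, s2 = 32, s3 = 33), amp = 2)
  tab <- facialDifferenceScore(lapply(sess, `[[`, "features"),
                               lapply(sess, `[[`, "trials"))
  ## event-locked displacement only after CS: positive difference score
  expect_true(all(tab$score > 0))
  expect_identical(tab$subject, c("s1", "s2", "s3"))
})

test_that("statistically identical pre and post dynamics score near zero", {
  ## zero facial amplitude: any score reflects jitter alone
  sess <- facialSessions(c(s1 = 41, s2 = 42, s3 = 43), amp = 0)
  tab <- facialDifferenceScore(lapply(sess, `[[`, "features"),
                               lapply(sess, `[[`, "trials"))
  sessOn <- facialSessions(c(s1 = 41, s2 = 42, s3 = 43), amp = 2)
  tabOn <- facialDifferenceScore(lapply(sessOn, `[[`, "features"),
                                 lapply(sessOn, `[[`, "trials"))
  expect_lt(mean(abs(tab$score)), mean(tabOn$score))
})

test_that("difference scores rise monotonically with planted amplitude", {
  amps <- c(0.5, 1.5, 3)
  means <- vapply(amps, function(a) {
    scores <- vapply(1:6, function(seed) {
      sess <- facialSessions(stats::setNames(100 * seed + 1:2,
                                             c("s1", "s2")), amp = a)
      mean(facialDifferenceScore(lapply(sess, `[[`, "features"),
                                 lapply(sess, `[[`, "trials"))$score)
    }, numeric(1))
    mean(scores)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("cloned subjects get identical difference scores", {
  sess <- facialSessions(c(s1 = 51), amp = 1.5)
  three <- list(s1 = sess[[1]]$features, s2 = sess[[1]]$features,
                s3 = sess[[1]]$features)
  trials <- list(s1 = sess[[1]]$trials, s2 = sess[[1]]$trials,
                 s3 = sess[[1]]$trials)
  tab <- facialDifferenceScore(three, trials)
  expect_equal(max(tab$score) - min(tab$score), 0, tolerance = 1e-10)
})
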