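test_that("local z-score normalizes each trial to its own baseline", {
  set.seed(1)
  arr <- array(rnorm(4 * 40 * 6, mean = 3, sd = 2), c(4, 40, 6))
  ten <- eventAlignedTensor(arr, binWidth = 0.5, window = c(-10, 10))
  z <- localZscore(ten, c(-10, 0))
  bb <- 1:20
  for (tr in c(1, 4)) {
    base <- tensorData(z)[, bb, tr]
    expect_equal(rowMeans(base), rep(0, 4), tolerance = 1e-10)
    expect_equal(apply(base, 1, sd), rep(1, 4), tolerance = 1e-10)
  }
  expect_false(any(z@flooredSd))
  expect_identical(z@zMode, "local")
})

test_that("constant traces z-score to zero with a floored-sd flag", {
  arr <- array(7, c(2, 10, 3))
  ten <- eventAlignedTensor(arr, binWidth = 1, window = c(-5, 5))
  z <- localZscore(ten, c(-5, 0))
  expect_true(all(tensorData(z) == 0))
  expect_true(all(z@flooredSd))
})

test_that("hand-built 5-bin trace matches direct z arithmetic", {
  arr <- array(c(1, 1, 3, 5, 7), c(1, 5, 1))
  ten <- eventAlignedTensor(arr, binWidth = 1, window = c(-2, 3))
  ## baseline = first two bins (values 1, 1): sd floored, flagged
  z0 <- localZscore(ten, c(-2, 0))
  expect_true(all(z0@flooredSd))
  ## baseline values {1, 3}: mean 2, sd sqrt(2) -> z for value 5 is 3/sqrt(2)
  arr2 <- array(c(1, 3, 5, 7, 9), c(1, 5, 1))
  z2 <- localZscore(eventAlignedTensor(arr2, binWidth = 1, window = c(-2, 3)),
                    c(-2, 0))
  expect_equal(tensorData(z2)[1, 3, 1], (5 - 2) / sqrt(2), tolerance = 1e-12)
  expect_error(localZscore(ten, c(-20, 0)), "inside")
})

test_that("z-scoring matches the loop oracle on random tensors", {
  set.seed(2)
  for (rep in 1:10) {
    arr <- array(rnorm(3 * 12 * 4), c(3, 12, 4))
    ten <- eventAlignedTensor(arr, binWidth = 1, window = c(-6, 6))
    got <- tensorData(localZscore(ten, c(-6, 0)))
    expect_equal(got, oracleLocalZ(arr, 1:6), tolerance = 1e-12)
  }
})

test_that("PCA captures rank-1 structure and is rotation invariant", {
  set.seed(3)
  u <- rnorm(6)
  mat <- outer(u, rnorm(30))          # rank 1 in unit space
  m <- fitPCA(mat)
  expect_equal(varianceFractions(m)[1], 1, tolerance = 1e-10)
  ## orthogonal rotation of the rows leaves the spectrum unchanged
  mat2 <- matrix(rnorm(6 * 30), 6)
  Q <- qr.Q(qr(matrix(rnorm(36), 6)))
  expect_equal(fitPCA(Q %*% mat2)@variances, fitPCA(mat2)@variances,
               tolerance = 1e-8)
  expect_error(fitPCA(matrix(1, 3, 10)), "degenerate")
})

test_that("isotropic clouds spread variance evenly across components", {
  set.seed(4)
  m <- fitPCA(matrix(rnorm(10 * 1e4), 10))
  expect_true(all(abs(varianceFractions(m) - 0.1) < 0.02))
  expect_equal(sum(varianceFractions(m)), 1, tolerance = 1e-10)
})

test_that("projection reproduces the centering and reconstruction identities", {
  set.seed(5)
  mat <- matrix(rnorm(5 * 20), 5)
  m <- fitPCA(mat)
  ## projecting the centering vector gives the origin
  tr0 <- projectTrajectory(m, matrix(m@center, 5, 8), nPcs = 3,
                           binWidth = 1, window = c(0, 8))
  expect_equal(max(abs(trajectoryPoints(tr0))), 0, tolerance = 1e-10)
  ## full-rank reconstruction of the training columns is exact
  k <- ncol(m@loadings)
  sc <- projectTrajectory(m, mat, nPcs = k, binWidth = 1, window = c(0, 20))
  rec <- m@loadings %*% t(trajectoryPoints(sc)) + m@center
  expect_equal(rec, mat, tolerance = 1e-8, ignore_attr = TRUE)
  ## small case matches hand matrix multiplication
  resp <- matrix(rnorm(5 * 6), 5)
  got <- trajectoryPoints(projectTrajectory(m, resp, nPcs = 2, binWidth = 1,
                                            window = c(0, 6)))
  expect_equal(got, t(resp - m@center) %*% m@loadings[, 1:2],
               tolerance = 1e-12)
  expect_error(projectTrajectory(m, resp[1:3, ], nPcs = 2), "unit dimension")
  expect_error(projectTrajectory(m, resp, nPcs = 99), "exceeds")
})

test_that("trajectory length matches geometry and the step oracle", {
  flat <- new("Trajectory", points = matrix(1, 10, 3), binWidth = 1,
              window = c(0, 10), label = "flat")
  expect_equal(trajectoryLength(flat), 0)
  seg <- new("Trajectory", points = rbind(c(0, 0), c(3, 4)), binWidth = 1,
             window = c(0, 2), label = "3-4-5")
  expect_equal(trajectoryLength(seg), 5)
  set.seed(6)
  rnd <- randomTrajectory(201, 23)
  expect_equal(trajectoryLength(rnd), oracleTrajLength(trajectoryPoints(rnd)),
               tolerance = 1e-10)
  expect_error(trajectoryLength(seg, c(0, 0.5)), "at least 2 bins")
})

test_that("trajectory distance matches the per-bin oracle", {
  a <- randomTrajectory(50, 4)
  expect_equal(trajectoryDistance(a, a)$perBin, rep(0, 50))
  b <- a
  b@points <- a@points + rep(c(1, 2, 2, 4), each = 50)
  expect_equal(trajectoryDistance(a, b)$perBin, rep(5, 50))
  set.seed(7)
  c1 <- randomTrajectory(30, 6)
  c2 <- randomTrajectory(30, 6)
  d <- trajectoryDistance(c1, c2)
  expect_equal(d$perBin,
               oracleTrajDistance(trajectoryPoints(c1), trajectoryPoints(c2)),
               tolerance = 1e-10)
  expect_equal(d$mean, mean(d$perBin))
  expect_error(trajectoryDistance(c1, randomTrajectory(29, 6)), "share")
})

test_that("length obeys the triangle, orthogonal and scaling laws", {
  set.seed(8)
  for (rep in 1:10) {
    tr <- randomTrajectory(40, 5)
    pts <- trajectoryPoints(tr)
    expect_gte(trajectoryLength(tr) + 1e-12,
               sqrt(sum((pts[40, ] - pts[1, ])^2)))
    Q <- qr.Q(qr(matrix(rnorm(25), 5)))
    trQ <- tr; trQ@points <- pts %*% Q
    expect_equal(trajectoryLength(trQ), trajectoryLength(tr),
                 tolerance = 1e-10)
    trS <- tr; trS@points <- 3.5 * pts
    expect_equal(trajectoryLength(trS), 3.5 * trajectoryLength(tr),
                 tolerance = 1e-10)
    ## distances are jointly invariant under the same rotation
    tr2 <- randomTrajectory(40, 5)
    tr2Q <- tr2; tr2Q@points <- trajectoryPoints(tr2) %*% Q
    expect_equal(trajectoryDistance(trQ, tr2Q)$perBin,
                 trajectoryDistance(tr, tr2)$perBin, tolerance = 1e-10)
  }
})

test_that("PC count for a variance fraction is minimal and monotone", {
  m <- new("PCModel", loadings = diag(4), variances = c(0.5, 0.3, 0.15, 0.05),
           totalVariance = 1, center = rep(0, 4))
  expect_identical(pcsForVariance(m, 0.5), 1L)
  expect_identical(pcsForVariance(m, 0.9), 3L)
  expect_identical(pcsForVariance(m, 1), 4L)
  m2 <- new("PCModel", loadings = diag(3), variances = c(0.6, 0.3, 0.1),
            totalVariance = 1, center = rep(0, 3))
  expect_identical(pcsForVariance(m2, 0.6), 1L)
  fr <- seq(0.05, 1, by = 0.05)
  counts <- vapply(fr, function(f) pcsForVariance(m, f), integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(pcsForVariance(m, 0), "fraction")
})

test_that("super-global z-score pools statistics across sessions", {
  set.seed(9)
  a <- neuralSession(matrix(rnorm(3 * 50, 5, 2), 3), 10, mouseId = "m1",
                     epoch = "baseline")
  b <- neuralSession(matrix(rnorm(3 * 70, 5, 2), 3), 10,
                     roiIds = roiIds(a), mouseId = "m1", epoch = "stress_w6")
  zs <- superGlobalZscore(list(a, b))
  pooled <- cbind(activityMatrix(zs[[1]]), activityMatrix(zs[[2]]))
  expect_equal(unname(rowMeans(pooled)), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(apply(pooled, 1, sd)), rep(1, 3), tolerance = 1e-10)
  ## per-session means are NOT re-centered individually
  expect_gt(max(abs(rowMeans(activityMatrix(zs[[1]])))), 1e-6)
})
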