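## Independent brute-force oracles and small fixtures shared across tests.
## Every oracle is a from-scratch implementation kept deliberately naive
## (explicit loops, textbook formulas) and independent of the package's
## code paths.

## Path length: explicit loop over adjacent point pairs.
oracleTrajLength <- function(points) {
  total <- 0
  for (i in seq_len(nrow(points) - 1L)) {
    step <- points[i + 1L, ] - points[i, ]
    total <- total + sqrt(sum(step^2))
  }
  total
}

## Bin-by-bin distance: explicit loop.
oracleTrajDistance <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) sqrt(sum((a[i, ] - b[i, ])^2)),
         numeric(1))
}

## Per-trial baseline z-score: explicit loops over units and trials.
oracleLocalZ <- function(arr, baselineBins) {
  out <- arr
  for (u in seq_len(dim(arr)[1])) {
    for (tr in seq_len(dim(arr)[3])) {
      base <- arr[u, baselineBins, tr]
      s <- stats::sd(base)
      if (s < 1e-9) s <- 1e-9
      out[u, , tr] <- (arr[u, , tr] - mean(base)) / s
    }
  }
  out
}

## Savitzky-Golay by least squares: fit a polynomial of order p on each
## (edge-truncated) window and evaluate at the target position.
oracleSavGol <- function(x, p, n) {
  N <- length(x)
  h <- (n - 1L) / 2L
  out <- numeric(N)
  for (t in seq_len(N)) {
    if (t <= h) {
      idx <- 1:n; at <- t
    } else if (t > N - h) {
      idx <- (N - n + 1L):N; at <- t - (N - n)
    } else {
      idx <- (t - h):(t + h); at <- h + 1L
    }
    co <- stats::lm.fit(outer(seq_len(n), 0:p, `^`), x[idx])$coefficients
    out[t] <- sum(co * at^(0:p))
  }
  out
}

## Polygon area by fan triangulation from the first vertex: each triangle's
## signed area from the cross product, summed, absolute value.
oraclePolyArea <- function(x, y) {
  total <- 0
  for (i in 2:(length(x) - 1L)) {
    ux <- x[i] - x[1]; uy <- y[i] - y[1]
    vx <- x[i + 1L] - x[1]; vy <- y[i + 1L] - y[1]
    total <- total + (ux * vy - uy * vx) / 2
  }
  abs(total)
}

## Finite-difference kinematics: explicit per-frame loop mirroring the
## documented scheme (central interior, one-sided ends, acceleration ends
## replicated).
oracleKinematics <- function(pos, fps) {
  nf <- nrow(pos)
  speed <- accel <- numeric(nf)
  for (t in seq_len(nf)) {
    v <- if (t == 1L) (pos[2, ] - pos[1, ]) * fps
         else if (t == nf) (pos[nf, ] - pos[nf - 1L, ]) * fps
         else (pos[t + 1L, ] - pos[t - 1L, ]) / 2 * fps
    speed[t] <- sqrt(sum(v^2))
  }
  for (t in 2:(nf - 1L)) {
    a <- (pos[t + 1L, ] - 2 * pos[t, ] + pos[t - 1L, ]) * fps^2
    accel[t] <- sqrt(sum(a^2))
  }
  accel[1] <- accel[2]
  accel[nf] <- accel[nf - 1L]
  list(speed = speed, accel = accel)
}

## Exhaustive 1-D k-means: minimum WCSS over every assignment of n points
## to k cluster ids (empty clusters allowed; they cannot beat the optimum).
oracleBestWcss <- function(x, k) {
  n <- length(x)
  best <- Inf
  for (code in 0:(k^n - 1L)) {
    assign <- integer(n)
    c0 <- code
    for (i in seq_len(n)) {
      assign[i] <- c0 %% k
      c0 <- c0 %/% k
    }
    w <- 0
    for (cl in 0:(k - 1L)) {
      pts <- x[assign == cl]
      if (length(pts)) w <- w + sum((pts - mean(pts))^2)
    }
    if (w < best) best <- w
  }
  best
}

## Small, fast session design used where full 48-trial sessions would be
## needlessly slow: 14 trials, short ITIs, same timing structure otherwise.
tinyDesign <- function() {
  sessionDesign(nReward = 8L, nRewardCatch = 1L, nPunish = 4L,
                nPunishCatch = 1L, itiRange = c(6, 9))
}

## Uniform phenotype with configurable planted gains.
flatPhenotype <- function(rewardGain = 1, punishGain = 1, facialAmp = 1,
                          antic = 2.5, cons = 6) {
  ones <- stats::setNames(rep(1, length(cmsEpochs())), cmsEpochs())
  phenotypeSpec("control",
                sptMeanByEpoch = ones * 85,
                rewardGainByEpoch = ones * rewardGain,
                punishGainByEpoch = ones * punishGain,
                facialAmpByEpoch = ones * facialAmp,
                lickAnticipatoryRate = antic, lickConsummatoryRate = cons)
}

randomTrajectory <- function(nBins, nDims, binWidth = 0.1, label = "rnd") {
  new("Trajectory", points = matrix(stats::rnorm(nBins * nDims), nBins),
      binWidth = binWidth, window = c(0, nBins * binWidth), label = label)
}
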