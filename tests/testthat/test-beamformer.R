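test_that("data covariance reflects the channel structure", {
  fs <- 312.5
  set.seed(1)
  T1 <- 30000
  rec <- sensorRecording(matrix(rnorm(2 * T1), 2), fs)
  C <- computeCovariance(rec)
  # independent channels: tiny off-diagonal correlation
  expect_lt(abs(C@matrix[1, 2]) / sqrt(C@matrix[1, 1] * C@matrix[2, 2]), 0.05)
  # diagonal near the band fraction of unit white-noise variance (the
  # Butterworth roll-off trims ~10% relative to a brick-wall band)
  expect_equal(unname(diag(C@matrix)), rep(47.5 / 156.25, 2), tolerance = 0.15)
  expect_identical(C@nSamples, as.integer(T1))
  # constant channels vanish after mean removal
  Cz <- computeCovariance(sensorRecording(matrix(1, 2, 600), fs))
  expect_equal(max(abs(Cz@matrix)), 0, tolerance = 1e-30)
  # duplicated channel: rank-deficiency warning
  x <- rnorm(3000)
  expect_warning(computeCovariance(sensorRecording(rbind(x, x), fs)),
                 "rank deficient|ill-conditioned")
  # too few samples for the channel count: warning, not failure
  expect_warning(computeCovariance(sensorRecording(matrix(rnorm(10 * 40), 10), fs)),
                 "5N")
  expect_error(computeCovariance(sensorRecording(matrix(0, 2, 1), fs)))
  expect_error(computeCovariance(rec, band = c(0.5, 200)), "invalid band")
})

test_that("source variance and weights match the hand-computed 2x2 oracle", {
  Cb <- diag(c(2, 1))
  L <- c(1, 1)
  # (L' C^-1 L)^-1 = (1/2 + 1)^-1 = 2/3
  expect_equal(sourceVariance(L, Cb), 2 / 3, tolerance = 1e-12)
  W <- computeWeights(L, Cb)
  expect_equal(as.numeric(W), c(1 / 3, 2 / 3), tolerance = 1e-12)
  # identity / scaling special cases
  expect_equal(sourceVariance(c(1, 0), diag(2)), 1, tolerance = 1e-12)
  expect_equal(sourceVariance(c(1, 1), 5 * diag(2)), 5 / 2, tolerance = 1e-12)
})

test_that("unit gain and projected-variance identities hold on random SPD covariances", {
  set.seed(2)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    Cb <- randomSPD(n)
    L <- rnorm(n)
    W <- computeWeights(L, Cb)
    expect_equal(sum(W * L), 1, tolerance = 1e-9)
    s2 <- drop(crossprod(W, Cb %*% W))
    expect_equal(s2, sourceVariance(L, Cb), tolerance = 1e-9)
  }
})

test_that("orientation eigensolution matches brute-force grid search", {
  hm <- testHead()
  sens <- makeSensorCap(24)
  set.seed(3)
  for (i in 1:100) {
    loc <- rnorm(3); loc <- loc / sqrt(sum(loc^2)) * runif(1, 0.02, 0.07)
    L <- leadField(hm, sens, loc)
    scl <- 1 / max(abs(L))           # work at O(1) scale
    Ls <- L * scl; attr(Ls, "basis") <- attr(L, "basis")
    Cb <- new("DataCovariance", matrix = randomSPD(24), nSamples = 1000L,
              band = c(0.5, 48))
    Sigma <- noiseCovariance(runif(24, 0.5, 2))
    theta <- optimalOrientation(Ls, Cb, Sigma)
    zEig <- pseudoZ(computeWeights(drop(Ls %*% attr(theta, "u")), Cb), Cb, Sigma)
    grid <- gridSearchOrientation(Ls, Cb, Sigma)
    expect_gte(zEig, grid$z * (1 - 1e-9))
  }
})

test_that("orientation recovers a planted dominant source and breaks ties deterministically", {
  hm <- testHead()
  sens <- makeSensorCap(24)
  L <- leadField(hm, sens, c(0.02, 0.01, 0.05))
  scl <- 1 / max(abs(L)); Ls <- L * scl; attr(Ls, "basis") <- attr(L, "basis")
  set.seed(4)
  for (i in 1:20) {
    ang <- runif(1, 0, pi)
    u <- c(cos(ang), sin(ang))
    g <- drop(Ls %*% u)
    Cb <- new("DataCovariance", matrix = diag(24) + 10 * tcrossprod(g),
              nSamples = 1000L, band = c(0.5, 48))
    theta <- optimalOrientation(Ls, Cb, noiseCovariance(1, 24))
    planted <- drop(attr(Ls, "basis") %*% u)
    # orientations are axial: compare up to sign
    ang_err <- acos(pmin(1, abs(sum(theta * planted))))
    expect_lt(ang_err, pi / 180)
  }
  # flat pseudo-Z profile: first tangential basis direction
  Cb <- new("DataCovariance", matrix = diag(24), nSamples = 1000L,
            band = c(0.5, 48))
  theta <- optimalOrientation(Ls, Cb, noiseCovariance(1, 24))
  expect_equal(abs(sum(theta * attr(Ls, "basis")[, 1])), 1, tolerance = 1e-9)
})

test_that("pseudo-Z scales as expected and ignores weight rescaling", {
  set.seed(5)
  n <- 10
  Sigma <- noiseCovariance(runif(n, 0.5, 2))
  W <- rnorm(n)
  expect_equal(pseudoZ(W, Sigma@matrix, Sigma), 1, tolerance = 1e-12)
  expect_equal(pseudoZ(W, 4 * Sigma@matrix, Sigma), 2, tolerance = 1e-12)
  Cb <- randomSPD(n)
  expect_equal(pseudoZ(W, Cb, Sigma), pseudoZ(10 * W, Cb, Sigma),
               tolerance = 1e-12)
})

test_that("weight normalisation preserves phase metrics exactly", {
  expect_equal(normalizeWeights(c(3, 4)), c(0.6, 0.8), tolerance = 1e-15)
  set.seed(6)
  W <- rnorm(20)
  expect_equal(sqrt(sum(normalizeWeights(W)^2)), 1, tolerance = 1e-12)
  expect_error(normalizeWeights(rep(0, 5)), "zero")
  # PLI from normalised vs unnormalised weights is identical
  rec <- sensorRecording(matrix(rnorm(20 * 8192), 20), 312.5)
  W2 <- rnorm(20)
  v1a <- bandpass(reconstructTimeseries(W, rec), c(8, 13), 312.5)
  v2a <- bandpass(reconstructTimeseries(W2, rec), c(8, 13), 312.5)
  v1b <- bandpass(reconstructTimeseries(normalizeWeights(W), rec), c(8, 13), 312.5)
  v2b <- bandpass(reconstructTimeseries(normalizeWeights(W2), rec), c(8, 13), 312.5)
  d_a <- instantaneousPhase(v1a) - instantaneousPhase(v2a)
  d_b <- instantaneousPhase(v1b) - instantaneousPhase(v2b)
  expect_equal(phaseLagIndex(d_a), phaseLagIndex(d_b), tolerance = 1e-12)
})

test_that("virtual electrode reconstruction is the weighted channel sum", {
  set.seed(7)
  rec <- sensorRecording(matrix(rnorm(5 * 1000), 5), 312.5)
  W <- c(1, 0, 0, 0, 0)
  expect_equal(reconstructTimeseries(W, rec), recordingData(rec)[1, ])
  # linearity in the data
  W <- rnorm(5)
  recB <- sensorRecording(2 * recordingData(rec) + 1e-3, 312.5)
  expect_equal(reconstructTimeseries(W, recB),
               2 * reconstructTimeseries(W, rec) + sum(W) * 1e-3,
               tolerance = 1e-12)
  expect_error(reconstructTimeseries(c(1, 2), rec), "match")
})

test_that("a simulated source is faithfully reconstructed at its own location", {
  hm <- testHead()
  sens <- makeSensorCap(60)
  src <- dipoleSource(hm, c(0.02, 0.01, 0.05))
  sig <- simulateSources(list(src), couplingSpec(carrierBand = c(8, 13)),
                         40, 312.5, seed = 8)
  rec <- projectSources(hm, sens, list(src), sig, noiseSd = 2e-14, seed = 9)
  Cb <- computeCovariance(rec)
  L <- leadField(hm, sens, src$location)
  theta <- optimalOrientation(L, Cb)
  W <- computeWeights(drop(L %*% attr(theta, "u")), Cb)
  V <- reconstructTimeseries(normalizeWeights(W), rec)
  expect_gte(abs(cor(V, sig[1, ])), 0.95)
})

test_that("pseudo-Z maps localise two distant uncorrelated sources", {
  hm <- testHead()
  sens <- makeSensorCap(80)
  locs <- rbind(c(0.035, 0, 0.045), c(-0.035, 0, 0.045))
  srcs <- list(dipoleSource(hm, locs[1, ]), dipoleSource(hm, locs[2, ]))
  sig <- simulateSources(srcs, couplingSpec(carrierBand = c(8, 13)),
                         40, 312.5, seed = 10)
  rec <- projectSources(hm, sens, srcs, sig, noiseSd = 5e-14, seed = 11)
  # voxel grid covering both sources at 10 mm spacing
  g <- as.matrix(expand.grid(x = seq(-0.05, 0.05, by = 0.01),
                             y = seq(-0.02, 0.02, by = 0.01),
                             z = seq(0.025, 0.065, by = 0.01)))
  parc <- parcellation(seq_len(nrow(g)), g, rep("ALL", nrow(g)))
  est <- computeSourceEstimates(rec, sens, hm, parc)
  z <- pseudoZValues(est)
  peak1 <- g[which.max(z), ]
  expect_lt(sqrt(sum((peak1 - locs[1, ])^2)), 0.0101 * sqrt(3) + 1e-9)
  # second source: peak among voxels far from the first source
  far <- sqrt(rowSums(sweep(g, 2, locs[1, ])^2)) > 0.03
  peak2 <- g[far, ][which.max(z[far]), ]
  expect_lt(sqrt(sum((peak2 - locs[2, ])^2)), 0.0101 * sqrt(3) + 1e-9)
})

test_that("weight normalisation equalises projected noise across depth", {
  hm <- testHead()
  sens <- makeSensorCap(60)
  set.seed(12)
  rec <- sensorRecording(matrix(rnorm(60 * 15000, sd = 5e-14), 60), 312.5,
                         channelIds = channelIds(sens))
  depths <- seq(0.02, 0.07, by = 0.01)
  parc <- parcellation(seq_along(depths),
                       cbind(0.01, 0, rev(depths)), rep("D", length(depths)))
  est <- computeSourceEstimates(rec, sens, hm, parc)
  W <- sourceWeights(est)
  vrUnnorm <- apply(W %*% recordingData(rec), 1, var)
  Wn <- W / sqrt(rowSums(W^2))
  vrNorm <- apply(Wn %*% recordingData(rec), 1, var)
  expect_lt(max(vrNorm) / min(vrNorm), 1.5)
  expect_gt(max(vrUnnorm) / min(vrUnnorm), 1.5)
})

test_that("weight correlation matrix equals direct pairwise correlations", {
  W <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(2, -1, 4, -5))
  R <- weightCorrelationMatrix(W)
  expect_equal(R[1, 2], 1, tolerance = 1e-12)
  expect_equal(diag(R), rep(0, 3))
  # orthogonal zero-mean vectors
  W2 <- rbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(weightCorrelationMatrix(W2)[1, 2], 0, tolerance = 1e-12)
  # random vectors vs element-wise oracle
  set.seed(13)
  W3 <- matrix(rnorm(3 * 30), 3)
  R3 <- weightCorrelationMatrix(W3)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(R3[i, j], cor(W3[i, ], W3[j, ])^2, tolerance = 1e-12)
  expect_true(isSymmetric(R3))
  expect_warning(weightCorrelationMatrix(rbind(rep(1, 4), rnorm(4))),
                 "constant")
})
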