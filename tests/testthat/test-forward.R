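test_that("tangential basis is orthonormal, radial-orthogonal and deterministic", {
  hm <- testHead()
  set.seed(1)
  for (i in 1:50) {
    loc <- runif(3, -0.05, 0.05)
    if (sqrt(sum(loc^2)) < 1e-3) next
    Tb <- tangentialBasis(hm, loc)
    expect_equal(colSums(Tb^2), c(1, 1), tolerance = 1e-12)
    expect_lt(abs(sum(Tb[, 1] * Tb[, 2])), 1e-12)
    radial <- loc / sqrt(sum(loc^2))
    expect_lt(max(abs(crossprod(Tb, radial))), 1e-12)
    expect_identical(Tb, tangentialBasis(hm, loc))
  }
  # +z axis: basis spans the x-y plane
  Tb <- tangentialBasis(hm, c(0, 0, 0.05))
  expect_equal(unname(Tb[3, ]), c(0, 0), tolerance = 1e-15)
  expect_error(tangentialBasis(hm, c(0, 0, 0)), "center")
  expect_error(tangentialBasis(hm, c(0, 0, 0.2)), "outside")
})

test_that("rotating the geometry rotates the tangential plane with it", {
  hm <- testHead()
  set.seed(2)
  for (i in 1:10) {
    loc <- c(0.02, -0.01, 0.04)
    R <- rotationMatrix(rnorm(3), runif(1, 0.1, 3))
    T1 <- tangentialBasis(hm, loc)
    T2 <- tangentialBasis(hm, drop(R %*% loc))
    # rotated original basis must lie in the span of the new basis
    proj <- T2 %*% crossprod(T2, R %*% T1)
    expect_equal(proj, R %*% T1, tolerance = 1e-10)
  }
})

test_that("radial component of the sphere lead field matches the Biot-Savart oracle", {
  hm <- testHead()
  set.seed(3)
  for (i in 1:100) {
    # one radially oriented sensor outside, one tangential dipole inside
    sdir <- rnorm(3); sdir <- sdir / sqrt(sum(sdir^2))
    spos <- sdir * runif(1, 0.1, 0.2)
    sens <- sensorArray(c("A", "B"), rbind(spos, c(0, 0, 0.3)),
                        rbind(sdir, c(0, 0, 1)))
    loc <- rnorm(3); loc <- loc / sqrt(sum(loc^2)) * runif(1, 0.01, 0.07)
    lf <- leadField(hm, sens, loc)
    Tb <- attr(lf, "basis")
    for (k in 1:2) {
      bs <- biotSavartDipole(Tb[, k] * 1e-9, loc, spos)
      expect_lte(abs(lf[1, k] - sum(bs * sdir)), 1e-10 * max(abs(lf)))
    }
  }
})

test_that("radially oriented dipoles are magnetically silent", {
  # The full sphere-model field for an arbitrary moment is the lead field
  # applied to the tangential components only, so the radial component of
  # the moment contributes nothing: fields from m and from its tangential
  # projection are identical, and a purely radial moment gives zero.
  hm <- testHead()
  sens <- makeSensorCap(50)
  set.seed(4)
  for (i in 1:100) {
    loc <- rnorm(3); loc <- loc / sqrt(sum(loc^2)) * runif(1, 0.02, 0.07)
    lf <- leadField(hm, sens, loc)
    radial <- loc / sqrt(sum(loc^2))
    u <- drop(crossprod(attr(lf, "basis"), radial))  # radial moment in basis coords
    expect_equal(max(abs(lf %*% u)), 0, tolerance = 1e-25)
  }
})

test_that("lead field transforms consistently under rotation of the whole configuration", {
  hm <- testHead()
  set.seed(5)
  R <- rotationMatrix(c(1, 2, -1), 0.9)
  pos <- rbind(c(0.12, 0, 0.05), c(0, 0.11, 0.06), c(-0.1, 0.02, 0.08))
  ori <- pos / sqrt(rowSums(pos^2))
  sens <- sensorArray(c("a", "b", "c"), pos, ori)
  sensR <- sensorArray(c("a", "b", "c"), t(R %*% t(pos)), t(R %*% t(ori)))
  loc <- c(0.02, 0.01, 0.05)
  lf <- leadField(hm, sens, loc)
  lfR <- leadField(hm, sensR, drop(R %*% loc))
  # compare fields of the same physical dipole: moment m and R m
  m <- attr(lf, "basis")[, 1]
  u1 <- drop(crossprod(attr(lf, "basis"), m))
  u2 <- drop(crossprod(attr(lfR, "basis"), drop(R %*% m)))
  expect_equal(drop(lf %*% u1), drop(lfR %*% u2), tolerance = 1e-12)
})

test_that("simulated couplings impose the requested phase lag", {
  # lag 0, strength 1: identical signals
  sig0 <- coupledPairSeries(0, 1, seed = 10)
  expect_equal(sig0[1, ], sig0[2, ], tolerance = 1e-10)
  # lag pi/2, strength 1: constant quarter-cycle phase difference
  sig <- coupledPairSeries(pi / 2, 1, seed = 11)
  ph1 <- instantaneousPhase(sig[1, ])
  ph2 <- instantaneousPhase(sig[2, ])
  interior <- 500:(ncol(sig) - 500)
  d <- megpli:::.wrapPhase(ph1 - ph2)[interior]
  circMean <- Arg(mean(exp(1i * d)))
  expect_lt(abs(circMean - pi / 2), 0.05)
  # circular concentration: nearly all mass at the planted lag
  expect_gt(Mod(mean(exp(1i * d))), 0.95)
})

test_that("strength-zero pairs behave like independent signals", {
  null <- independentPairPLINull(n = 150, S = 16384)
  q95 <- quantile(null, 0.95, names = FALSE)
  below <- vapply(1:40, function(s) {
    sig <- coupledPairSeries(pi / 4, 0, seed = 600 + s, duration = 53)
    d <- instantaneousPhase(sig[1, 1:16384]) - instantaneousPhase(sig[2, 1:16384])
    phaseLagIndex(d) <= q95
  }, logical(1))
  expect_gte(mean(below), 0.85)
})

test_that("source simulation is bit-reproducible given the seed", {
  a <- coupledPairSeries(pi / 3, 0.7, seed = 42)
  b <- coupledPairSeries(pi / 3, 0.7, seed = 42)
  expect_identical(a, b)
  c <- coupledPairSeries(pi / 3, 0.7, seed = 43)
  expect_false(identical(a, c))
})

test_that("projection superposes linearly and adds calibrated noise", {
  hm <- testHead()
  sens <- makeSensorCap(30)
  s1 <- dipoleSource(hm, c(0.02, 0, 0.04))
  s2 <- dipoleSource(hm, c(-0.03, 0.01, 0.03))
  cs <- couplingSpec(carrierBand = c(8, 13))
  sig <- simulateSources(list(s1, s2), cs, 40, 312.5, seed = 7)
  # single source, no noise: every channel is a scalar multiple of the source
  r1 <- projectSources(hm, sens, list(s1), sig[1, , drop = FALSE], fs = 312.5)
  cc <- abs(cor(t(recordingData(r1)), sig[1, ]))
  expect_true(all(cc > 1 - 1e-10))
  # two sources, no noise: exact superposition
  r2 <- projectSources(hm, sens, list(s2), sig[2, , drop = FALSE], fs = 312.5)
  r12 <- projectSources(hm, sens, list(s1, s2), sig)
  expect_equal(recordingData(r12), recordingData(r1) + recordingData(r2),
               tolerance = 1e-12)
  # noise calibration: residual sd within 5% of the requested level
  rn <- projectSources(hm, sens, list(s1, s2), sig, noiseSd = 3e-14, seed = 9)
  resid <- recordingData(rn) - recordingData(r12)
  expect_equal(sd(resid), 3e-14, tolerance = 0.05)
  # identical seed, identical noise
  rn2 <- projectSources(hm, sens, list(s1, s2), sig, noiseSd = 3e-14, seed = 9)
  expect_identical(recordingData(rn), recordingData(rn2))
  expect_error(projectSources(hm, sens, list(s1), sig), "S x T")
})

test_that("toy parcellation builds disjoint labelled voxel sets inside the sphere", {
  hm <- testHead()
  p1 <- makeToyParcellation(hm, K = 1, voxelsPerRoi = 1, seed = 1)
  expect_length(p1@voxelIds, 1L)
  p <- makeToyParcellation(hm, K = 10, voxelsPerRoi = 5, spacing = 5, seed = 2)
  expect_length(p@voxelIds, 50L)
  expect_length(roiLabels(p), 10L)
  expect_equal(as.vector(table(p@voxelLabels)), rep(5L, 10))
  expect_false(anyDuplicated(p@voxelIds) > 0)
  radii <- sqrt(rowSums(p@positions^2))
  expect_true(all(radii < hm@radius))
  expect_identical(p, makeToyParcellation(hm, 10, 5, spacing = 5, seed = 2))
  expect_error(makeToyParcellation(hm, K = 1000, voxelsPerRoi = 100,
                                   spacing = 20, seed = 1),
               "cannot fit")
})
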