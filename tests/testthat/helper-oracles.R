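# Independent oracles and shared fixtures for the test suite. The oracles
# are deliberately written from first principles (free-space magnetostatics,
# explicit textbook formulas, brute-force searches) so they never share code
# with the implementation they check.

# Free-space magnetic field of a current dipole (Biot-Savart law for the
# primary current only): B(r) = mu0/(4 pi) * Q x (r - r0) / |r - r0|^3.
# Q in A m, positions in metres, output Tesla.
biotSavartDipole <- function(q, r0, r) {
  d <- r - r0
  n3 <- sum(d^2)^1.5
  1e-7 * c(q[2] * d[3] - q[3] * d[2],
           q[3] * d[1] - q[1] * d[3],
           q[1] * d[2] - q[2] * d[1]) / n3
}

# 3D rotation matrix about an arbitrary axis (Rodrigues formula).
rotationMatrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  Kx <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * Kx + (1 - cos(angle)) * Kx %*% Kx
}

# Random symmetric positive-definite matrix.
randomSPD <- function(n) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) + diag(n) * 0.1
}

# Brute-force orientation search: evaluate the pseudo-Z through the
# exported weight/pseudo-Z operations on a dense tangential angle grid.
gridSearchOrientation <- function(L, Cb, Sigma, stepDeg = 0.1) {
  angles <- seq(0, pi, by = stepDeg * pi / 180)
  best <- -Inf; bestU <- c(1, 0)
  for (a in angles) {
    u <- c(cos(a), sin(a))
    W <- computeWeights(drop(L %*% u), Cb)
    z <- pseudoZ(W, Cb, Sigma)
    if (z > best) { best <- z; bestU <- u }
  }
  list(z = best, u = bestU)
}

# Standard synthetic geometry used across tests.
testHead <- function() headModel(c(0, 0, 0), 0.09)

# A small coupled-pair ROI series fixture: returns a 2 x T matrix of
# narrowband signals with the requested lag/strength.
coupledPairSeries <- function(lag, strength, seed, duration = 66,
                              fs = 312.5, band = c(8, 13)) {
  hm <- testHead()
  srcs <- list(dipoleSource(hm, c(0.02, 0, 0.04)),
               dipoleSource(hm, c(-0.02, 0, 0.04)))
  cs <- couplingSpec(data.frame(i = 1L, j = 2L, lag = lag,
                                strength = strength),
                     carrierBand = band)
  simulateSources(srcs, cs, duration, fs, seed = seed)
}

# Null distribution of the PLI of two independent narrowband series
# (Monte-Carlo; used as the reference for "indistinguishable from
# independent" assertions).
independentPairPLINull <- function(n = 200, S = 8192, fs = 312.5,
                                   band = c(8, 13), seed = 424) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    x <- megpli:::.bandNoise(S, band, fs)
    y <- megpli:::.bandNoise(S, band, fs)
    d <- instantaneousPhase(x) - instantaneousPhase(y)
    phaseLagIndex(d)
  }, numeric(1))
}
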