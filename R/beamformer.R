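## Scalar (SAM-style) minimum-variance beamformer.
##
## For a target location with tangential lead field L (N x 2) and band-
## limited data covariance Cb, the source variance along orientation theta
## is sigma2 = (L_theta' Cb^-1 L_theta)^-1, the unit-gain weights are
## W = sigma2 * L_theta' Cb^-1, and the orientation is chosen to maximise
## the pseudo-Z ratio (W Cb W') / (W Sigma W') with Sigma the sensor noise
## covariance. Covariance inversion uses a pseudo-inverse with relative
## eigenvalue truncation at 1e-12; no noise regularisation by default.

#' Band-limited sensor data covariance
#'
#' Sample covariance (divisor T - 1) of the zero-phase band-passed,
#' mean-removed channels. Broadband 0.5-48 Hz is the default analysis band
#' for weight estimation, which avoids overestimating between-channel
#' covariance relative to narrowband windows.
#'
#' @param recording a [SensorRecording-class].
#' @param band numeric(2) passband, Hz.
#' @param regularize Tikhonov factor lambda; when positive,
#'   `lambda * trace(C)/N` is added to the diagonal (off by default).
#' @return a [DataCovariance-class].
#' @export
computeCovariance <- function(recording, band = c(0.5, 48), regularize = 0) {
  X <- recording@data
  n <- nrow(X); T1 <- ncol(X)
  if (T1 < 2) stop("need at least 2 samples for a covariance estimate")
  .checkBand(band, recording@fs)
  if (T1 < 5 * n)
    warning(sprintf("only %d samples for %d channels (< 5N); covariance may be poorly conditioned", T1, n))
  X <- X - rowMeans(X)        # remove DC before filtering (no step transient)
  Xf <- bandpass(X, band, recording@fs)
  Xf <- Xf - rowMeans(Xf)
  C <- tcrossprod(Xf) / (T1 - 1)
  C <- (C + t(C)) / 2
  if (regularize > 0)
    C <- C + diag(regularize * sum(diag(C)) / n, n)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) > 0 && min(ev) < 1e-12 * max(ev))
    warning("data covariance is rank deficient or severely ill-conditioned")
  new("DataCovariance", matrix = C, nSamples = as.integer(T1), band = band)
}

#' Estimate a diagonal sensor noise covariance from the data covariance
#'
#' Default noise model: white sensor noise at the level of the smallest
#' data-covariance eigenvalue (the noise floor visible in the quietest
#' spatial component).
#'
#' @param Cb a [DataCovariance-class].
#' @return a [NoiseCovariance-class].
#' @export
estimateNoiseCovariance <- function(Cb) {
  ev <- eigen(Cb@matrix, symmetric = TRUE, only.values = TRUE)$values
  noiseCovariance(max(min(ev), 1e-30 * max(ev)), nrow(Cb@matrix))
}

#' Beamformer source variance
#'
#' `sigma2 = (L_theta' Cb^-1 L_theta)^-1`: the estimated variance of a
#' source at the target location/orientation, the crux of the minimum-
#' variance beamformer.
#'
#' @param Ltheta N-vector lead field along the chosen orientation, T/nAm.
#' @param Cb a [DataCovariance-class] (or plain matrix).
#' @return positive scalar, nAm^2.
#' @export
sourceVariance <- function(Ltheta, Cb) {
  C <- if (is(Cb, "DataCovariance")) Cb@matrix else Cb
  Ci <- .pinv(C)
  q <- drop(crossprod(Ltheta, Ci %*% Ltheta))
  if (q <= 0) stop("degenerate lead field / covariance combination")
  1 / q
}

#' Optimal tangential source orientation by pseudo-Z
#'
#' Finds the tangential-plane orientation maximising the pseudo-Z ratio,
#' solved in closed form as a 2 x 2 generalised eigenproblem in the
#' tangential coordinates of the lead field. The orientation sign is fixed
#' so that the first non-negligible component is positive (source polarity
#' is not observable). A flat pseudo-Z profile (degenerate case) returns
#' the first tangential basis direction.
#'
#' @param L N x 2 lead field from [leadField()] (attribute `"basis"`
#'   required to map back to a 3-vector).
#' @param Cb a [DataCovariance-class].
#' @param Sigma a [NoiseCovariance-class]; default estimated from `Cb`.
#' @return unit tangential 3-vector with the 2-vector tangential
#'   coordinates attached as attribute `"u"`.
#' @export
optimalOrientation <- function(L, Cb, Sigma = estimateNoiseCovariance(Cb)) {
  if (qr(L)$rank < 2)
    stop("rank-deficient lead field (location too close to the sphere center?)")
  Tb <- attr(L, "basis")
  Ci <- .pinv(Cb@matrix)
  CiL <- Ci %*% L
  A <- crossprod(L, CiL)                       # L' Ci L
  B <- crossprod(CiL, Sigma@matrix %*% CiL)    # L' Ci Sigma Ci L
  M <- solve(B, A)
  e <- eigen(M)
  lam <- Re(e$values)
  if (abs(lam[1] - lam[2]) <= 1e-9 * max(abs(lam), 1e-300)) {
    u <- c(1, 0)                               # flat profile: deterministic tie-break
  } else {
    u <- Re(e$vectors[, which.max(lam)])
    u <- u / sqrt(sum(u^2))
  }
  theta <- .fixSign(.unit(drop(Tb %*% u)))
  attr(theta, "u") <- drop(crossprod(Tb, theta))
  theta
}

#' Unit-gain beamformer weights
#'
#' `W = sigma2 * L_theta' Cb^-1`, satisfying `W L_theta = 1` (unit gain)
#' and `W Cb W' = sigma2` (projected variance identity).
#'
#' @param Ltheta N-vector lead field along the source orientation.
#' @param Cb a [DataCovariance-class] (or plain matrix).
#' @return numeric N-vector of weights, nAm/T, with `sigma2` attached as
#'   attribute.
#' @export
computeWeights <- function(Ltheta, Cb) {
  C <- if (is(Cb, "DataCovariance")) Cb@matrix else Cb
  Ci <- .pinv(C)
  CiL <- drop(Ci %*% Ltheta)
  q <- sum(Ltheta * CiL)
  if (q <= 0) stop("degenerate lead field / covariance combination")
  W <- CiL / q
  attr(W, "sigma2") <- 1 / q
  W
}

#' Normalise beamformer weights by their vector norm
#'
#' Beamformer weights grow with source depth while sensor noise is constant
#' across the volume, so reconstructed deep series carry inflated noise.
#' Dividing the weight vector by its norm equalises the projected noise
#' across depths; the reconstructed series changes only by a positive
#' scale, leaving all phase-based quantities untouched.
#'
#' @param W numeric weight vector.
#' @return unit-norm weight vector.
#' @export
normalizeWeights <- function(W) {
  n <- sqrt(sum(W^2))
  if (n == 0) stop("cannot normalise zero weights")
  as.numeric(W) / n
}

#' Reconstruct a virtual-electrode time-series
#'
#' `V = W B`: the weighted sum of all channels at every sample.
#'
#' @param W numeric N-vector of weights, nAm/T.
#' @param recording a [SensorRecording-class].
#' @return numeric T-vector, nAm (or nAm-proportional units for
#'   norm-normalised weights).
#' @export
reconstructTimeseries <- function(W, recording) {
  if (length(W) != nrow(recording@data))
    stop(sprintf("weight length %d does not match %d channels",
                 length(W), nrow(recording@data)))
  drop(as.numeric(W) %*% recording@data)
}

#' Pseudo-Z statistic
#'
#' `sqrt((W Cb W') / (W Sigma W'))`: beamformer output power normalised by
#' projected sensor-noise power; invariant to rescaling of the weights.
#'
#' @param W numeric weight vector.
#' @param Cb a [DataCovariance-class] (or plain matrix).
#' @param Sigma a [NoiseCovariance-class] (or plain matrix).
#' @return non-negative scalar.
#' @export
pseudoZ <- function(W, Cb, Sigma) {
  C <- if (is(Cb, "DataCovariance")) Cb@matrix else Cb
  S <- if (is(Sigma, "NoiseCovariance")) Sigma@matrix else Sigma
  W <- as.numeric(W)
  num <- drop(crossprod(W, C %*% W))
  den <- drop(crossprod(W, S %*% W))
  if (den <= 0) stop("zero projected noise power")
  sqrt(num / den)
}

#' Beamform all parcellation voxels
#'
#' Computes the band-limited data covariance once, then per voxel: the
#' tangential lead field, the pseudo-Z optimal orientation, the unit-gain
#' weights, the source variance and the pseudo-Z statistic.
#'
#' @param recording a [SensorRecording-class].
#' @param sensors a [SensorArray-class] matching the recording channels.
#' @param head a [HeadModel-class].
#' @param parcel a [Parcellation-class].
#' @param band numeric(2) covariance band, Hz (default broadband 0.5-48).
#' @param regularize optional Tikhonov factor for the covariance.
#' @param Sigma optional [NoiseCovariance-class]; default estimated from
#'   the data covariance.
#' @return a [SourceEstimateSet-class].
#' @export
computeSourceEstimates <- function(recording, sensors, head, parcel,
                                   band = c(0.5, 48), regularize = 0,
                                   Sigma = NULL) {
  if (!identical(sensors@ids, recording@channelIds))
    stop("sensor array and recording channels do not match")
  Cb <- computeCovariance(recording, band = band, regularize = regularize)
  if (is.null(Sigma)) Sigma <- estimateNoiseCovariance(Cb)
  Ci <- .pinv(Cb@matrix)
  V <- length(parcel@voxelIds)
  N <- length(sensors@ids)
  Wmat <- matrix(0, V, N)
  orient <- matrix(0, V, 3)
  sig2 <- numeric(V); pz <- numeric(V)
  for (v in seq_len(V)) {
    L <- leadField(head, sensors, parcel@positions[v, ])
    Tb <- attr(L, "basis")
    CiL <- Ci %*% L
    A <- crossprod(L, CiL)
    B <- crossprod(CiL, Sigma@matrix %*% CiL)
    e <- eigen(solve(B, A))
    lam <- Re(e$values)
    if (abs(lam[1] - lam[2]) <= 1e-9 * max(abs(lam), 1e-300)) {
      u <- c(1, 0)
    } else {
      u <- Re(e$vectors[, which.max(lam)])
      u <- u / sqrt(sum(u^2))
    }
    theta <- .fixSign(.unit(drop(Tb %*% u)))
    u <- drop(crossprod(Tb, theta))
    Lt <- drop(L %*% u)
    CiLt <- drop(CiL %*% u)
    q <- sum(Lt * CiLt)
    sig2[v] <- 1 / q
    W <- CiLt / q
    Wmat[v, ] <- W
    orient[v, ] <- theta
    pz[v] <- sqrt(drop(crossprod(W, Cb@matrix %*% W)) /
                    drop(crossprod(W, Sigma@matrix %*% W)))
  }
  new("SourceEstimateSet", voxelIds = parcel@voxelIds,
      orientations = orient, weights = Wmat, sigma2 = sig2, pseudoZ = pz,
      band = band, channelIds = recording@channelIds)
}

#' Squared correlation between beamformer weight vectors
#'
#' Diagnostic of beamformer field spread: entry (i, j) is the squared
#' Pearson correlation between the weight vectors of units i and j, with
#' the diagonal set to zero. High weight correlation means two virtual
#' electrodes sample overlapping sensor patterns, which produces spurious
#' zero-lag coupling between their reconstructed series.
#'
#' @param W K x N matrix of weight vectors (rows), or a
#'   [SourceEstimateSet-class].
#' @return K x K symmetric matrix in `[0, 1]`, zero diagonal. Constant
#'   weight vectors give NA entries with a warning.
#' @export
weightCorrelationMatrix <- function(W) {
  if (is(W, "SourceEstimateSet")) W <- W@weights
  W <- as.matrix(W)
  sds <- apply(W, 1, stats::sd)
  if (any(sds == 0))
    warning("constant weight vector(s): correlation undefined, entries set to NA")
  R <- suppressWarnings(stats::cor(t(W)))^2
  diag(R) <- 0
  R
}
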