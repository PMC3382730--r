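## Analytic spherical forward model and the seeded synthetic-data generator.

#' Tangential basis at a source location
#'
#' Returns two orthonormal vectors spanning the plane orthogonal to the
#' radial direction at `location`. In a spherical conductor only the
#' tangential dipole moment produces an external magnetic field, so the
#' lead field has (at most) these two effective columns. The construction
#' rule is deterministic: the coordinate axis least aligned with the radial
#' direction seeds the first tangential vector.
#'
#' @param head a [HeadModel-class].
#' @param location numeric(3) source position, metres.
#' @return 3 x 2 matrix whose columns are the tangential unit vectors.
#' @export
tangentialBasis <- function(head, location) {
  r0 <- as.numeric(location) - head@center
  d <- sqrt(sum(r0^2))
  if (d < 1e-12)
    stop("degenerate geometry: source at the sphere center")
  if (d >= head@radius)
    stop("source location lies outside the head sphere")
  radial <- r0 / d
  e <- diag(3)[, which.min(abs(radial))]
  t1 <- .unit(.crossprod3(e, radial))
  t2 <- .crossprod3(radial, t1)
  cbind(t1, t2, deparse.level = 0)
}

#' Magnetic lead field of a tangential dipole in a conducting sphere
#'
#' Closed-form field of a current dipole inside a homogeneous conducting
#' sphere, evaluated at the sensor positions and projected onto the sensor
#' orientations. Columns correspond to unit dipoles (1 nAm) along the two
#' tangential basis directions of [tangentialBasis()]; a radially oriented
#' dipole is magnetically silent in this model.
#'
#' @param head a [HeadModel-class].
#' @param sensors a [SensorArray-class]; every sensor must lie strictly
#'   outside the sphere.
#' @param location numeric(3) source position, metres.
#' @return N x 2 matrix, Tesla per nAm, with the 3 x 2 tangential basis
#'   attached as attribute `"basis"`.
#' @export
leadField <- function(head, sensors, location) {
  Tb <- tangentialBasis(head, location)  # also validates the geometry
  P <- sweep(sensors@positions, 2, head@center)
  if (any(sqrt(rowSums(P^2)) <= head@radius))
    stop("all sensors must lie strictly outside the head sphere")
  r0 <- as.numeric(location) - head@center
  lf <- matrix(0, nrow(P), 2)
  avec <- sweep(P, 2, r0)
  a <- sqrt(rowSums(avec^2))
  rr <- sqrt(rowSums(P^2))
  adotr <- rowSums(avec * P)
  r0dotr <- drop(P %*% r0)
  FF <- a * (rr * a + rr^2 - r0dotr)
  c1 <- a^2 / rr + adotr / a + 2 * a + 2 * rr
  c2 <- a + 2 * rr + adotr / a
  gradF <- c1 * P - outer(c2, r0)
  for (k in 1:2) {
    Q <- Tb[, k] * 1e-9  # 1 nAm in A m
    Qxr0 <- .crossprod3(Q, r0)
    B <- (FF * matrix(Qxr0, nrow(P), 3, byrow = TRUE) -
            drop(P %*% Qxr0) * gradF) * (1e-7 / FF^2)
    lf[, k] <- rowSums(B * sensors@orientations)
  }
  attr(lf, "basis") <- Tb
  lf
}

#' Hemispherical cap of radial magnetometers
#'
#' Default synthetic sensor fixture: `n` point magnetometers on the upper
#' hemisphere of a sphere of radius `radius`, radially oriented, arranged on
#' a Fibonacci lattice (deterministic).
#'
#' @param n number of channels (default 150, echoing a 151-channel
#'   whole-head system).
#' @param radius sensor shell radius, metres.
#' @param center shell center, metres.
#' @return a [SensorArray-class].
#' @export
makeSensorCap <- function(n = 150, radius = 0.11, center = c(0, 0, 0)) {
  i <- seq_len(n)
  # Fibonacci lattice on the upper hemisphere (z in (0, 1])
  z <- (i - 0.5) / n
  phi <- pi * (1 + sqrt(5)) * i
  st <- sqrt(1 - z^2)
  dirs <- cbind(st * cos(phi), st * sin(phi), z)
  pos <- sweep(dirs * radius, 2, center, "+")
  sensorArray(sprintf("MEG%03d", i), pos, dirs)
}

#' Construct a dipole source
#'
#' @param head a [HeadModel-class].
#' @param location numeric(3), metres; strictly inside the sphere and away
#'   from the center.
#' @param moment unit tangential 3-vector (orthogonal to the radial
#'   direction within 1e-9 after normalisation); defaults to the first
#'   tangential basis vector at `location`.
#' @param amplitude source amplitude, nAm (scales the unit-variance signal; default 20 nAm, a physiological cortical source strength).
#' @return list of class `DipoleSource`.
#' @export
dipoleSource <- function(head, location, moment = NULL, amplitude = 20) {
  Tb <- tangentialBasis(head, location)  # validates the location
  radial <- .unit(as.numeric(location) - head@center)
  if (is.null(moment)) {
    moment <- Tb[, 1]
  } else {
    moment <- .unit(as.numeric(moment))
    if (abs(sum(moment * radial)) > 1e-9)
      stop("dipole moment must be tangential (orthogonal to the radial direction)")
  }
  if (amplitude <= 0) stop("amplitude must be positive")
  structure(list(location = as.numeric(location), moment = moment,
                 amplitude = amplitude),
            class = "DipoleSource")
}

#' Specify pairwise phase-lag couplings between simulated sources
#'
#' @param pairs data.frame with columns `i`, `j` (source indices, `i != j`),
#'   `lag` (radians, in (-pi, pi]) and `strength` (fraction in `[0, 1]`).
#'   May have zero rows for fully independent sources.
#' @param carrierBand numeric(2) carrier band in Hz shared by all sources,
#'   or an S x 2 matrix with one band per source.
#' @param noiseFraction fraction in `[0, 1)` of independent same-band noise
#'   mixed into every source signal.
#' @return list of class `CouplingSpec`.
#' @export
couplingSpec <- function(pairs = data.frame(i = integer(), j = integer(),
                                            lag = numeric(),
                                            strength = numeric()),
                         carrierBand = c(8, 13), noiseFraction = 0) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs)) {
    stopifnot(all(c("i", "j", "lag", "strength") %in% names(pairs)))
    if (any(pairs$i == pairs$j)) stop("coupling requires i != j")
    if (any(pairs$lag <= -pi | pairs$lag > pi))
      stop("lag must lie in (-pi, pi]")
    if (any(pairs$strength < 0 | pairs$strength > 1))
      stop("strength must lie in [0, 1]")
  }
  if (noiseFraction < 0 || noiseFraction >= 1)
    stop("noiseFraction must lie in [0, 1)")
  structure(list(pairs = pairs, carrierBand = carrierBand,
                 noiseFraction = noiseFraction),
            class = "CouplingSpec")
}

## Narrowband unit-variance noise: white Gaussian filtered into `band`.
.bandNoise <- function(n, band, fs) {
  x <- .bandpassVector(stats::rnorm(n), band, fs)
  x / stats::sd(x)
}

## Rotate the analytic signal: output phase = input phase - lag at every
## sample (exact carrier phase shift for narrowband signals).
.phaseShift <- function(x, lag) {
  Re(.analytic(x) * exp(-1i * lag))
}

#' Simulate coupled narrowband dipole source signals
#'
#' Generates one unit-variance band-limited Gaussian signal per source, then
#' imposes the requested couplings: for a pair `(i, j, lag, strength)` the
#' target signal becomes the `strength`-weighted, `lag`-phase-shifted copy
#' of the driver plus `(1 - strength)`-weighted independent same-band noise,
#' restandardised and scaled by the source amplitude (nAm). With
#' `strength = 1` and no noise the analytic-signal phase difference between
#' the pair equals `lag` at every sample.
#'
#' @param sources list of [dipoleSource()] objects.
#' @param coupling a [couplingSpec()].
#' @param duration seconds; `duration * fs` must be at least 4096.
#' @param fs sampling rate, Hz.
#' @param seed integer seed; identical seeds give identical signals.
#' @return S x T matrix of source amplitudes, nAm; attribute `"fs"`.
#' @export
simulateSources <- function(sources, coupling, duration, fs, seed) {
  S <- length(sources)
  n <- round(duration * fs)
  if (n < 4096) stop("duration * fs must be at least 4096 samples")
  cb <- coupling$carrierBand
  bands <- if (is.matrix(cb)) cb else matrix(cb, S, 2, byrow = TRUE)
  for (s in seq_len(S)) .checkBand(bands[s, ], fs)
  set.seed(seed)
  sig <- matrix(0, S, n)
  for (s in seq_len(S)) sig[s, ] <- .bandNoise(n, bands[s, ], fs)
  prs <- coupling$pairs
  if (nrow(prs)) {
    for (p in seq_len(nrow(prs))) {
      i <- prs$i[p]; j <- prs$j[p]
      w <- prs$strength[p]
      shifted <- .phaseShift(sig[i, ], prs$lag[p])
      mixed <- w * shifted + (1 - w) * .bandNoise(n, bands[j, ], fs)
      sig[j, ] <- mixed / stats::sd(mixed)
    }
  }
  nf <- coupling$noiseFraction
  if (nf > 0) {
    for (s in seq_len(S)) {
      mixed <- (1 - nf) * sig[s, ] + nf * .bandNoise(n, bands[s, ], fs)
      sig[s, ] <- mixed / stats::sd(mixed)
    }
  }
  amp <- vapply(sources, function(x) x$amplitude, numeric(1))
  out <- sig * amp
  attr(out, "fs") <- fs
  out
}

#' Project source signals to the sensors
#'
#' Superposes the spherical-model dipolar field patterns of all sources,
#' sample by sample, and adds independent Gaussian sensor noise.
#'
#' @param head a [HeadModel-class].
#' @param sensors a [SensorArray-class].
#' @param sources list of [dipoleSource()] objects (length S).
#' @param signals S x T matrix of source amplitudes, nAm (e.g. from
#'   [simulateSources()]).
#' @param noiseSd per-channel sensor noise standard deviation, Tesla.
#' @param seed integer seed for the noise draw (required when
#'   `noiseSd > 0`).
#' @param fs sampling rate recorded in the output; defaults to the
#'   `"fs"` attribute of `signals`.
#' @return a [SensorRecording-class].
#' @export
projectSources <- function(head, sensors, sources, signals, noiseSd = 0,
                           seed = NULL, fs = attr(signals, "fs")) {
  S <- length(sources)
  if (!is.matrix(signals) || nrow(signals) != S)
    stop(sprintf("signals must be an S x T matrix with S = %d rows, got %d",
                 S, NROW(signals)))
  if (is.null(fs)) stop("sampling rate not supplied")
  N <- length(sensors@ids)
  ## gain vector per source: field of its unit dipole along the moment
  G <- matrix(0, N, S)
  for (s in seq_len(S)) {
    lf <- leadField(head, sensors, sources[[s]]$location)
    u <- drop(crossprod(attr(lf, "basis"), sources[[s]]$moment))
    G[, s] <- lf %*% u
  }
  data <- G %*% signals
  if (noiseSd > 0) {
    if (is.null(seed)) stop("seed required when noiseSd > 0")
    set.seed(seed)
    data <- data + matrix(stats::rnorm(length(data), sd = noiseSd),
                          nrow(data), ncol(data))
  }
  sensorRecording(data, fs, sensors@ids)
}

#' Generate a toy source-space parcellation
#'
#' Places `K` compact, disjoint clusters of grid voxels inside the head
#' sphere, standing in for an anatomical atlas. ROI seed locations are
#' drawn (seeded) from a regular grid restricted to 85% of the sphere
#' radius; each ROI then claims its `voxelsPerRoi` nearest unclaimed grid
#' points.
#'
#' @param head a [HeadModel-class].
#' @param K number of ROIs.
#' @param voxelsPerRoi voxels per ROI.
#' @param spacing grid spacing in millimetres (default 5).
#' @param seed integer seed.
#' @return a [Parcellation-class].
#' @export
makeToyParcellation <- function(head, K, voxelsPerRoi, spacing = 5, seed = 1) {
  sp <- spacing / 1000
  rmax <- 0.85 * head@radius
  g <- seq(-rmax, rmax, by = sp)
  grid <- as.matrix(expand.grid(x = g, y = g, z = g))
  grid <- grid[sqrt(rowSums(grid^2)) <= rmax & sqrt(rowSums(grid^2)) > 0.2 * head@radius, , drop = FALSE]
  grid <- sweep(grid, 2, head@center, "+")
  if (nrow(grid) < K * voxelsPerRoi)
    stop("cannot fit the requested voxels inside the sphere at this spacing")
  set.seed(seed)
  centers <- grid[sample(nrow(grid), K), , drop = FALSE]
  claimed <- rep(FALSE, nrow(grid))
  pos <- matrix(0, K * voxelsPerRoi, 3)
  lab <- character(K * voxelsPerRoi)
  idx <- 1L
  for (k in seq_len(K)) {
    d <- sqrt(rowSums(sweep(grid, 2, centers[k, ])^2))
    d[claimed] <- Inf
    take <- order(d)[seq_len(voxelsPerRoi)]
    if (any(!is.finite(d[take])))
      stop("cannot fit the requested voxels inside the sphere at this spacing")
    claimed[take] <- TRUE
    rng <- idx:(idx + voxelsPerRoi - 1L)
    pos[rng, ] <- grid[take, , drop = FALSE]
    lab[rng] <- sprintf("ROI%02d", k)
    idx <- idx + voxelsPerRoi
  }
  parcellation(seq_len(K * voxelsPerRoi), pos, lab)
}
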