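## Frequency bands, zero-phase filtering, band power, representative-voxel
## selection and ROI time-series assembly.

#' The five classical EEG/MEG frequency bands
#'
#' delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30 and gamma 30-48 Hz.
#'
#' @return data.frame with columns `name`, `lo`, `hi` (Hz).
#' @export
defaultBands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             lo = c(0.5, 4, 8, 13, 30),
             hi = c(4, 8, 13, 30, 48),
             stringsAsFactors = FALSE)
}

.checkScheme <- function(scheme, fs) {
  stopifnot(is.data.frame(scheme), all(c("name", "lo", "hi") %in% names(scheme)))
  for (b in seq_len(nrow(scheme))) .checkBand(c(scheme$lo[b], scheme$hi[b]), fs)
  scheme
}

## 4th-order Butterworth, forward-backward (zero-phase) on a vector.
## Coefficients come from signal::butter; the forward-backward pass runs
## in compiled code (reflective end padding, direct-form II transposed).
.bandpassVector <- function(x, band, fs) {
  bf <- signal::butter(4, c(band[1], band[2]) / (fs / 2), type = "pass")
  .filtfiltVec(bf$b, bf$a, x)
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward and backward, so the filter cannot
#' introduce phase lags that a lag-sensitive connectivity estimator would
#' score. Accepts a vector or a matrix (rows are series).
#'
#' @param x numeric vector or matrix (series in rows).
#' @param band numeric(2), passband in Hz.
#' @param fs sampling rate, Hz.
#' @return filtered data, same shape as `x`.
#' @export
bandpass <- function(x, band, fs) {
  .checkBand(band, fs)
  bf <- signal::butter(4, c(band[1], band[2]) / (fs / 2), type = "pass")
  if (is.matrix(x)) .filtfiltRows(bf$b, bf$a, x)
  else .filtfiltVec(bf$b, bf$a, x)
}

#' Band power of a series
#'
#' Variance of the zero-phase band-passed series (equivalent to the
#' integrated power spectral density over the band).
#'
#' @param x numeric vector, at least 256 samples.
#' @param band numeric(2), Hz.
#' @param fs sampling rate, Hz.
#' @return non-negative power (signal units squared).
#' @export
bandPower <- function(x, band, fs) {
  if (length(x) < 256) stop("series too short for band power (need >= 256 samples)")
  y <- bandpass(x, band, fs)
  mean((y - mean(y))^2)
}

#' Relative band power
#'
#' Band power divided by the total power in the analysis passband
#' (default 0.5-48 Hz, the band used for the beamformer weights).
#'
#' @param x numeric vector.
#' @param band numeric(2), Hz.
#' @param fs sampling rate, Hz.
#' @param total numeric(2), the normalising passband in Hz.
#' @return fraction in `[0, 1]`.
#' @export
relativePower <- function(x, band, fs, total = c(0.5, 48)) {
  tot <- bandPower(x, total, fs)
  if (tot == 0) stop("zero total power in the normalising band")
  min(1, bandPower(x, band, fs) / tot)
}

#' Select the maximum-power voxel of a ROI in one band
#'
#' Ties are broken by the lowest voxel id. Selection is performed
#' independently per band (and per subject in multi-subject analyses).
#'
#' @param series V x T matrix of voxel virtual-electrode series.
#' @param voxelIds integer ids for the rows of `series`.
#' @param band numeric(2), Hz.
#' @param fs sampling rate, Hz.
#' @return list with `voxelId` and the band-passed `series` of the winner.
#' @export
selectRepresentativeVoxel <- function(series, voxelIds, band, fs) {
  if (NROW(series) < 1) stop("empty ROI")
  series <- rbind(series)
  filt <- bandpass(series, band, fs)
  p <- apply(filt, 1, function(r) mean((r - mean(r))^2))
  best <- which(p == max(p))
  best <- best[which.min(voxelIds[best])]
  list(voxelId = voxelIds[best], series = filt[best, ])
}

#' Assemble band-wise ROI representative time-series
#'
#' Reconstructs every voxel's virtual electrode through its vector-norm
#' normalised beamformer weights, band-passes it into each band of the
#' scheme, and keeps, per ROI and band, the voxel with maximum band power.
#' Voxel series are never averaged within a ROI: the estimated source
#' polarity at each voxel is arbitrary, so averaging could cancel signal.
#'
#' @param recording a [SensorRecording-class].
#' @param estimates a [SourceEstimateSet-class] with weights for every
#'   parcellation voxel.
#' @param parcel a [Parcellation-class].
#' @param scheme band scheme data.frame (default [defaultBands()]).
#' @return a [ROITimeSeriesSet-class].
#' @export
extractROISeries <- function(recording, estimates, parcel,
                             scheme = defaultBands()) {
  fs <- recording@fs
  .checkScheme(scheme, fs)
  if (!all(parcel@voxelIds %in% estimates@voxelIds))
    stop("missing beamformer weights for some parcellation voxels")
  ord <- match(parcel@voxelIds, estimates@voxelIds)
  W <- estimates@weights[ord, , drop = FALSE]
  Wn <- W / sqrt(rowSums(W^2))
  V <- Wn %*% recording@data            # voxels x T virtual electrodes
  K <- length(parcel@roiLabels)
  nT <- ncol(V)
  serList <- vector("list", nrow(scheme))
  names(serList) <- scheme$name
  chosen <- matrix(NA_integer_, K, nrow(scheme),
                   dimnames = list(parcel@roiLabels, scheme$name))
  relPow <- matrix(NA_real_, K, nrow(scheme),
                   dimnames = dimnames(chosen))
  totPow <- apply(bandpass(V, c(0.5, min(48, fs / 2 * 0.99)), fs), 1,
                  function(r) mean((r - mean(r))^2))
  for (b in seq_len(nrow(scheme))) {
    band <- c(scheme$lo[b], scheme$hi[b])
    Vf <- bandpass(V, band, fs)
    pw <- apply(Vf, 1, function(r) mean((r - mean(r))^2))
    M <- matrix(0, K, nT)
    for (k in seq_len(K)) {
      rows <- which(parcel@voxelLabels == parcel@roiLabels[k])
      p <- pw[rows]
      best <- rows[which(p == max(p))]
      best <- best[which.min(parcel@voxelIds[best])]
      chosen[k, b] <- parcel@voxelIds[best]
      M[k, ] <- Vf[best, ]
      relPow[k, b] <- min(1, pw[best] / totPow[best])
    }
    serList[[b]] <- M
  }
  new("ROITimeSeriesSet", series = serList, chosenVoxel = chosen,
      relativePower = relPow, bands = scheme,
      roiLabels = parcel@roiLabels, fs = fs)
}

#' Relative-power map of a ROI time-series set
#'
#' For each ROI and band, the fraction of the broadband (0.5-48 Hz) power
#' of that ROI's chosen voxel that falls within the band; computed during
#' [extractROISeries()].
#'
#' @param roiSet a [ROITimeSeriesSet-class].
#' @return K x B matrix of fractions.
#' @export
relativePowerMap <- function(roiSet) {
  roiSet@relativePower
}
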