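#' @import methods
NULL

## Central S4 containers. Geometry is stored in SI units (metres, Tesla);
## parcellation files on disk use millimetres (see read/writeParcellation).

#' Spherical volume-conductor head model
#'
#' A single homogeneous conducting sphere used for analytic magnetic lead
#' fields. For MEG the sphere model has the useful property that radially
#' oriented dipoles are magnetically silent, so only the two tangential
#' moment components are estimated per source location.
#'
#' @slot center numeric(3), sphere center in metres.
#' @slot radius positive scalar, sphere radius in metres.
#' @export
setClass("HeadModel",
  representation(center = "numeric", radius = "numeric"))

setValidity("HeadModel", function(object) {
  if (length(object@center) != 3L || !all(is.finite(object@center)))
    return("center must be a finite 3-vector")
  if (length(object@radius) != 1L || !is.finite(object@radius) ||
      object@radius <= 0)
    return("radius must be a positive scalar")
  TRUE
})

#' @param center numeric(3) sphere center, metres.
#' @param radius sphere radius, metres.
#' @rdname HeadModel-class
#' @export
headModel <- function(center = c(0, 0, 0), radius = 0.09) {
  new("HeadModel", center = as.numeric(center), radius = as.numeric(radius))
}

#' MEG sensor array
#'
#' Point magnetometers with a position and a unit orientation each; the
#' recorded signal per channel is the projection of the magnetic field onto
#' the channel orientation.
#'
#' @slot ids character vector of unique channel identifiers.
#' @slot positions N x 3 matrix, metres.
#' @slot orientations N x 3 matrix of unit vectors.
#' @export
setClass("SensorArray",
  representation(ids = "character", positions = "matrix",
                 orientations = "matrix"))

setValidity("SensorArray", function(object) {
  n <- length(object@ids)
  if (n < 2L) return("need at least 2 channels")
  if (anyDuplicated(object@ids)) return("channel ids must be unique")
  if (!identical(dim(object@positions), c(n, 3L)))
    return("positions must be an N x 3 matrix")
  if (!identical(dim(object@orientations), c(n, 3L)))
    return("orientations must be an N x 3 matrix")
  nrm <- sqrt(rowSums(object@orientations^2))
  if (any(abs(nrm - 1) > 1e-9))
    return("orientations must be unit vectors (within 1e-9)")
  TRUE
})

#' @param ids character channel ids.
#' @param positions N x 3 matrix of positions, metres.
#' @param orientations N x 3 matrix of unit orientations.
#' @rdname SensorArray-class
#' @export
sensorArray <- function(ids, positions, orientations) {
  new("SensorArray", ids = as.character(ids),
      positions = unname(as.matrix(positions)),
      orientations = unname(as.matrix(orientations)))
}

#' Multichannel sensor recording
#'
#' @slot data N x T matrix of magnetic field values, Tesla.
#' @slot fs sampling rate, Hz.
#' @slot channelIds channel identifiers matching the rows of `data`.
#' @export
setClass("SensorRecording",
  representation(data = "matrix", fs = "numeric", channelIds = "character"))

setValidity("SensorRecording", function(object) {
  if (!all(is.finite(object@data))) return("data must be finite")
  if (length(object@fs) != 1L || object@fs <= 0)
    return("fs must be a positive scalar")
  if (nrow(object@data) != length(object@channelIds))
    return("row count must match channelIds")
  TRUE
})

#' @param data N x T numeric matrix, Tesla.
#' @param fs sampling rate, Hz.
#' @param channelIds channel ids (default CH001, ...).
#' @rdname SensorRecording-class
#' @export
sensorRecording <- function(data, fs,
                            channelIds = sprintf("CH%03d", seq_len(nrow(data)))) {
  new("SensorRecording", data = unname(as.matrix(data)), fs = as.numeric(fs),
      channelIds = as.character(channelIds))
}

#' Voxel-to-ROI parcellation
#'
#' A set of labelled source-space voxels; each voxel carries exactly one ROI
#' label. Positions are stored in metres (files on disk use millimetres).
#'
#' @slot voxelIds integer voxel identifiers (unique).
#' @slot positions V x 3 matrix, metres.
#' @slot voxelLabels character ROI label per voxel.
#' @slot roiLabels ordered unique ROI labels.
#' @export
setClass("Parcellation",
  representation(voxelIds = "integer", positions = "matrix",
                 voxelLabels = "character", roiLabels = "character"))

setValidity("Parcellation", function(object) {
  v <- length(object@voxelIds)
  if (anyDuplicated(object@voxelIds)) return("voxel ids must be unique")
  if (!identical(dim(object@positions), c(v, 3L)))
    return("positions must be a V x 3 matrix")
  if (length(object@voxelLabels) != v)
    return("one label per voxel required")
  if (anyDuplicated(object@roiLabels)) return("ROI labels must be unique")
  if (!all(object@voxelLabels %in% object@roiLabels))
    return("voxel labels must be drawn from roiLabels")
  if (!all(object@roiLabels %in% object@voxelLabels))
    return("every ROI must contain at least one voxel")
  TRUE
})

#' @param voxelIds integer voxel ids.
#' @param positions V x 3 matrix, metres.
#' @param voxelLabels ROI label per voxel.
#' @param roiLabels ordered unique labels (default: order of first appearance).
#' @rdname Parcellation-class
#' @export
parcellation <- function(voxelIds, positions, voxelLabels,
                         roiLabels = unique(voxelLabels)) {
  new("Parcellation", voxelIds = as.integer(voxelIds),
      positions = unname(as.matrix(positions)),
      voxelLabels = as.character(voxelLabels),
      roiLabels = as.character(roiLabels))
}

#' Band-limited sensor data covariance
#'
#' @slot matrix N x N covariance, Tesla^2.
#' @slot nSamples number of samples the estimate is based on.
#' @slot band numeric(2), the passband in Hz.
#' @export
setClass("DataCovariance",
  representation(matrix = "matrix", nSamples = "integer", band = "numeric"))

setValidity("DataCovariance", function(object) {
  M <- object@matrix
  if (nrow(M) != ncol(M)) return("covariance must be square")
  sc <- max(abs(M))
  if (sc > 0 && max(abs(M - t(M))) > 1e-12 * sc)
    return("covariance must be symmetric (1e-12 relative)")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev)))
    return("covariance must be positive semi-definite")
  TRUE
})

#' Diagonal sensor noise covariance
#'
#' @slot matrix N x N diagonal matrix, Tesla^2.
#' @export
setClass("NoiseCovariance", representation(matrix = "matrix"))

setValidity("NoiseCovariance", function(object) {
  M <- object@matrix
  if (nrow(M) != ncol(M)) return("noise covariance must be square")
  if (any(M[row(M) != col(M)] != 0))
    return("off-diagonal entries must be exactly zero")
  if (any(diag(M) <= 0)) return("diagonal entries must be positive")
  TRUE
})

#' @param sigma2 per-channel noise variance (scalar or length-N), Tesla^2.
#' @param n number of channels.
#' @rdname NoiseCovariance-class
#' @export
noiseCovariance <- function(sigma2, n = length(sigma2)) {
  new("NoiseCovariance", matrix = diag(rep_len(as.numeric(sigma2), n), n))
}

#' Per-voxel beamformer solutions
#'
#' One row per source-space voxel: the optimised tangential orientation, the
#' unit-gain spatial-filter weights (nAm/T), the estimated source variance
#' and the pseudo-Z statistic.
#'
#' @slot voxelIds integer voxel ids.
#' @slot orientations V x 3 unit tangential orientations.
#' @slot weights V x N weight matrix, nAm/T (unit gain, unnormalised).
#' @slot sigma2 estimated source variance per voxel, nAm^2.
#' @slot pseudoZ pseudo-Z statistic per voxel.
#' @slot band numeric(2) band used for the covariance, Hz.
#' @slot channelIds channel ids matching the weight columns.
#' @export
setClass("SourceEstimateSet",
  representation(voxelIds = "integer", orientations = "matrix",
                 weights = "matrix", sigma2 = "numeric", pseudoZ = "numeric",
                 band = "numeric", channelIds = "character"))

setValidity("SourceEstimateSet", function(object) {
  v <- length(object@voxelIds)
  if (nrow(object@weights) != v || nrow(object@orientations) != v ||
      length(object@sigma2) != v || length(object@pseudoZ) != v)
    return("inconsistent number of voxels across slots")
  if (ncol(object@weights) != length(object@channelIds))
    return("weight columns must match channelIds")
  if (any(object@sigma2 <= 0)) return("sigma2 must be positive")
  if (any(object@pseudoZ < 0)) return("pseudo-Z must be non-negative")
  TRUE
})

#' Per-band ROI representative time-series
#'
#' For each frequency band, a K x T matrix holding the band-passed virtual
#' electrode of the maximum-power voxel of each ROI, plus the identity of
#' that chosen voxel.
#'
#' @slot series named list of K x T matrices (one per band), nAm.
#' @slot chosenVoxel K x B integer matrix of selected voxel ids.
#' @slot relativePower K x B matrix: per ROI and band, the fraction of the
#'   chosen voxel's broadband (0.5-48 Hz) power that falls in the band.
#' @slot bands data.frame with columns name, lo, hi (Hz).
#' @slot roiLabels ROI labels matching the matrix rows.
#' @slot fs sampling rate, Hz.
#' @export
setClass("ROITimeSeriesSet",
  representation(series = "list", chosenVoxel = "matrix",
                 relativePower = "matrix",
                 bands = "data.frame", roiLabels = "character",
                 fs = "numeric"))

setValidity("ROITimeSeriesSet", function(object) {
  if (length(object@series) != nrow(object@bands))
    return("one series matrix per band required")
  k <- length(object@roiLabels)
  for (m in object@series) {
    if (nrow(m) != k) return("each band matrix must have K rows")
    if (!all(is.finite(m))) return("series must be finite")
  }
  if (!identical(dim(object@chosenVoxel),
                 c(k, length(object@series))))
    return("chosenVoxel must be K x nBands")
  TRUE
})

#' ROI-by-ROI connectivity matrix
#'
#' @slot values K x K symmetric matrix in `[0, 1]`, zero diagonal.
#' @slot estimator "pli" or "pc".
#' @slot level "epoch", "subject" or "group".
#' @slot band band name the matrix belongs to ("" if unspecified).
#' @slot roiLabels ROI labels.
#' @export
setClass("AdjacencyMatrix",
  representation(values = "matrix", estimator = "character",
                 level = "character", band = "character",
                 roiLabels = "character"))

setValidity("AdjacencyMatrix", function(object) {
  M <- object@values
  if (nrow(M) != ncol(M)) return("adjacency must be square")
  if (max(abs(M - t(M))) > 1e-12) return("adjacency must be symmetric")
  if (any(diag(M) != 0)) return("diagonal must be zero")
  if (any(M < 0 | M > 1)) return("entries must lie in [0, 1]")
  if (!object@estimator %in% c("pli", "pc"))
    return("estimator must be 'pli' or 'pc'")
  if (length(object@roiLabels) != nrow(M))
    return("roiLabels must match matrix dimension")
  TRUE
})

#' @param values K x K matrix.
#' @param estimator "pli" or "pc".
#' @param level aggregation level.
#' @param band band name.
#' @param roiLabels ROI labels (default ROI01, ...).
#' @rdname AdjacencyMatrix-class
#' @export
adjacencyMatrix <- function(values, estimator, level = "epoch", band = "",
                            roiLabels = sprintf("ROI%02d", seq_len(nrow(values)))) {
  new("AdjacencyMatrix", values = unname(as.matrix(values)),
      estimator = estimator, level = level, band = band,
      roiLabels = as.character(roiLabels))
}

#' Max-statistic surrogate null distribution
#'
#' @slot values R maxima (over ROIs) of group-mean node strength, one per
#'   phase-randomised surrogate realisation.
#' @slot R number of realisations.
#' @slot seed base seed used.
#' @slot estimator "pli" or "pc".
#' @export
setClass("NullDistribution",
  representation(values = "numeric", R = "integer", seed = "integer",
                 estimator = "character"))

setValidity("NullDistribution", function(object) {
  if (object@R < 1L) return("need at least one realisation")
  if (length(object@values) != object@R)
    return("values must have length R")
  if (any(object@values < 0 | object@values > 1))
    return("null values must lie in [0, 1]")
  TRUE
})

#' ROI significance map from a max-statistic null
#'
#' @slot pValues per-ROI p-values in (0, 1].
#' @slot significant logical per ROI, `pValues <= alpha`.
#' @slot alpha significance level.
#' @slot roiLabels ROI labels.
#' @export
setClass("SignificanceMap",
  representation(pValues = "numeric", significant = "logical",
                 alpha = "numeric", roiLabels = "character"))

setValidity("SignificanceMap", function(object) {
  if (any(object@pValues <= 0 | object@pValues > 1))
    return("p-values must lie in (0, 1]")
  if (!identical(object@significant, object@pValues <= object@alpha))
    return("significant must equal pValues <= alpha")
  TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "HeadModel", function(object) {
  cat(sprintf("HeadModel sphere: center (%g, %g, %g) m, radius %g m\n",
              object@center[1], object@center[2], object@center[3],
              object@radius))
})

setMethod("show", "SensorArray", function(object) {
  cat(sprintf("SensorArray with %d channels\n", length(object@ids)))
})

setMethod("show", "SensorRecording", function(object) {
  cat(sprintf("SensorRecording: %d channels x %d samples at %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@fs,
              ncol(object@data) / object@fs))
})

setMethod("show", "Parcellation", function(object) {
  cat(sprintf("Parcellation: %d voxels in %d ROIs\n",
              length(object@voxelIds), length(object@roiLabels)))
})

setMethod("show", "DataCovariance", function(object) {
  cat(sprintf("DataCovariance: %d x %d, %d samples, band %g-%g Hz\n",
              nrow(object@matrix), ncol(object@matrix), object@nSamples,
              object@band[1], object@band[2]))
})

setMethod("show", "SourceEstimateSet", function(object) {
  cat(sprintf("SourceEstimateSet: %d voxels x %d channels, band %g-%g Hz\n",
              length(object@voxelIds), ncol(object@weights),
              object@band[1], object@band[2]))
  cat(sprintf("  pseudo-Z range: %.3g - %.3g\n",
              min(object@pseudoZ), max(object@pseudoZ)))
})

setMethod("show", "ROITimeSeriesSet", function(object) {
  cat(sprintf("ROITimeSeriesSet: %d ROIs x %d samples at %g Hz, %d bands (%s)\n",
              length(object@roiLabels), ncol(object@series[[1]]), object@fs,
              nrow(object@bands), paste(object@bands$name, collapse = ", ")))
})

setMethod("show", "AdjacencyMatrix", function(object) {
  off <- object@values[row(object@values) != col(object@values)]
  cat(sprintf("AdjacencyMatrix (%s, %s level%s): %d ROIs, mean %.4f\n",
              toupper(object@estimator), object@level,
              if (nzchar(object@band)) paste0(", ", object@band) else "",
              nrow(object@values), mean(off)))
})

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf("NullDistribution (%s): R = %d, 95th percentile %.4f\n",
              toupper(object@estimator), object@R,
              stats::quantile(object@values, 0.95, names = FALSE)))
})

setMethod("show", "SignificanceMap", function(object) {
  cat(sprintf("SignificanceMap: %d / %d ROIs significant at alpha = %g\n",
              sum(object@significant), length(object@pValues), object@alpha))
})

## ---- accessors ----------------------------------------------------------

#' Accessors for megpli containers
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "SensorRecording", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "ROITimeSeriesSet", function(x) x@fs)

#' @rdname accessors
#' @export
setGeneric("channelIds", function(x) standardGeneric("channelIds"))
#' @rdname accessors
#' @export
setMethod("channelIds", "SensorRecording", function(x) x@channelIds)
#' @rdname accessors
#' @export
setMethod("channelIds", "SensorArray", function(x) x@ids)

#' @rdname accessors
#' @export
setGeneric("recordingData", function(x) standardGeneric("recordingData"))
#' @rdname accessors
#' @export
setMethod("recordingData", "SensorRecording", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))
#' @rdname accessors
#' @export
setMethod("roiLabels", "Parcellation", function(x) x@roiLabels)
#' @rdname accessors
#' @export
setMethod("roiLabels", "ROITimeSeriesSet", function(x) x@roiLabels)
#' @rdname accessors
#' @export
setMethod("roiLabels", "AdjacencyMatrix", function(x) x@roiLabels)

#' @rdname accessors
#' @export
setGeneric("adjacencyValues", function(x) standardGeneric("adjacencyValues"))
#' @rdname accessors
#' @export
setMethod("adjacencyValues", "AdjacencyMatrix", function(x) {
  v <- x@values
  dimnames(v) <- list(x@roiLabels, x@roiLabels)
  v
})

#' @rdname accessors
#' @export
setGeneric("bandSeries", function(x, band) standardGeneric("bandSeries"))

#' @rdname accessors
#' @param band band name, e.g. "alpha".
#' @export
setMethod("bandSeries", "ROITimeSeriesSet", function(x, band) {
  if (!band %in% names(x@series))
    stop("unknown band: ", band)
  m <- x@series[[band]]
  rownames(m) <- x@roiLabels
  m
})

#' @rdname accessors
#' @export
setGeneric("nullValues", function(x) standardGeneric("nullValues"))
#' @rdname accessors
#' @export
setMethod("nullValues", "NullDistribution", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))
#' @rdname accessors
#' @export
setMethod("pValues", "SignificanceMap", function(x) {
  stats::setNames(x@pValues, x@roiLabels)
})

#' @rdname accessors
#' @export
setGeneric("isSignificant", function(x) standardGeneric("isSignificant"))
#' @rdname accessors
#' @export
setMethod("isSignificant", "SignificanceMap", function(x) {
  stats::setNames(x@significant, x@roiLabels)
})

#' @rdname accessors
#' @export
setGeneric("sourceWeights", function(x) standardGeneric("sourceWeights"))
#' @rdname accessors
#' @export
setMethod("sourceWeights", "SourceEstimateSet", function(x) {
  w <- x@weights
  rownames(w) <- x@voxelIds
  colnames(w) <- x@channelIds
  w
})

#' @rdname accessors
#' @export
setGeneric("pseudoZValues", function(x) standardGeneric("pseudoZValues"))
#' @rdname accessors
#' @export
setMethod("pseudoZValues", "SourceEstimateSet", function(x) {
  stats::setNames(x@pseudoZ, x@voxelIds)
})

#' @rdname accessors
#' @export
setGeneric("sourceVariances", function(x) standardGeneric("sourceVariances"))
#' @rdname accessors
#' @export
setMethod("sourceVariances", "SourceEstimateSet", function(x) {
  stats::setNames(x@sigma2, x@voxelIds)
})
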