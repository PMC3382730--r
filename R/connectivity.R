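## Phase-based functional connectivity: instantaneous phase, Phase
## Coherence, Phase Lag Index, epoch/subject averaging, node strength.

#' Instantaneous phase of a band-limited series
#'
#' Phase of the analytic signal (frequency-domain Hilbert transform),
#' wrapped to `[-pi, pi)`. Meaningful for band-limited input (bandwidth
#' below the center frequency recommended).
#'
#' @param x numeric vector.
#' @return phase series in radians.
#' @export
instantaneousPhase <- function(x) {
  if (all(x == 0)) stop("cannot extract phase from an all-zero series")
  .wrapPhase(Arg(.analytic(x)))
}

#' Phase Coherence
#'
#' `PC = |mean(exp(i * dphi))|`: the modulus of the mean complex phase
#' difference. Equals 1 iff the phase difference is constant; sensitive to
#' both zero-lag and lagged coupling, and therefore to volume conduction
#' and field spread.
#'
#' @param dphi numeric vector of phase differences, radians.
#' @return value in `[0, 1]`.
#' @export
phaseCoherence <- function(dphi) {
  if (length(dphi) < 2) stop("need at least 2 phase-difference samples")
  Mod(mean(exp(1i * dphi)))
}

#' Phase Lag Index
#'
#' `PLI = |mean(sign(sin(dphi)))|` with `sign(0) = 0`: non-zero only when
#' the distribution of phase differences is asymmetric around zero (and
#' pi), i.e. when there is a consistent non-zero phase lag. Exactly-zero
#' lags contribute nothing, which is what makes the index insensitive to
#' volume conduction and beamformer field spread.
#'
#' @param dphi numeric vector of phase differences, radians.
#' @return value in `[0, 1]`.
#' @export
phaseLagIndex <- function(dphi) {
  if (length(dphi) < 2) stop("need at least 2 phase-difference samples")
  abs(mean(sign(sin(dphi))))
}

## Estimator on a K x S matrix of per-ROI instantaneous phases. Runs in
## compiled code on unit phasors: with w = exp(i(ph_i - ph_j)),
## PC = |mean(w)| and sign(sin(ph_i - ph_j)) = sign(Im w), identical to
## the angular forms for any interval convention.
.pairwiseFromPhases <- function(ph, estimator) {
  .pairwisePhaseCpp(ph, estimator == "pli")
}

#' Per-epoch connectivity matrices for one band
#'
#' Splits the ROI series into the first `nEpochs` non-overlapping segments
#' of `epochLength` samples, extracts instantaneous phases per segment, and
#' evaluates the estimator for every ROI pair.
#'
#' @param x K x T matrix of band-limited ROI series, or a
#'   [ROITimeSeriesSet-class] together with `band`.
#' @param estimator "pli" or "pc".
#' @param epochLength samples per epoch (default 4096, i.e. 13.1 s at
#'   312.5 Hz).
#' @param nEpochs number of epochs (default 5).
#' @param band band name when `x` is a [ROITimeSeriesSet-class].
#' @param roiLabels optional ROI labels for a matrix input.
#' @return list of per-epoch [AdjacencyMatrix-class] objects.
#' @export
epochAdjacency <- function(x, estimator = c("pli", "pc"),
                           epochLength = 4096, nEpochs = 5, band = "",
                           roiLabels = NULL) {
  estimator <- match.arg(estimator)
  if (is(x, "ROITimeSeriesSet")) {
    if (!band %in% names(x@series)) stop("unknown band: ", band)
    roiLabels <- x@roiLabels
    x <- x@series[[band]]
  }
  if (!is.matrix(x)) stop("x must be a K x T matrix or a ROITimeSeriesSet")
  if (is.null(roiLabels)) roiLabels <- sprintf("ROI%02d", seq_len(nrow(x)))
  if (ncol(x) < nEpochs * epochLength)
    stop(sprintf("need %d samples for %d epochs of %d, have %d",
                 nEpochs * epochLength, nEpochs, epochLength, ncol(x)))
  lapply(seq_len(nEpochs), function(e) {
    idx <- ((e - 1) * epochLength + 1):(e * epochLength)
    ph <- .wrapPhase(Arg(.analyticRows(x[, idx, drop = FALSE])))
    adjacencyMatrix(.pairwiseFromPhases(ph, estimator), estimator,
                    level = "epoch", band = band, roiLabels = roiLabels)
  })
}

#' Average adjacency matrices over epochs and subjects
#'
#' A flat list of [AdjacencyMatrix-class] objects is averaged directly
#' (epochs within one subject, level "subject"). A list of such lists is
#' averaged per subject first and then across subjects (level "group"), so
#' subjects with unequal epoch counts still contribute equally.
#'
#' @param x list of [AdjacencyMatrix-class], or list of lists of them.
#' @return an [AdjacencyMatrix-class].
#' @export
averageAdjacency <- function(x) {
  if (length(x) == 0) stop("empty input")
  if (is(x[[1]], "AdjacencyMatrix")) {
    tmpl <- x[[1]]
    vals <- Reduce(`+`, lapply(x, function(a) a@values)) / length(x)
    return(adjacencyMatrix(vals, tmpl@estimator, level = "subject",
                           band = tmpl@band, roiLabels = tmpl@roiLabels))
  }
  subj <- lapply(x, averageAdjacency)
  tmpl <- subj[[1]]
  vals <- Reduce(`+`, lapply(subj, function(a) a@values)) / length(subj)
  adjacencyMatrix(vals, tmpl@estimator, level = "group",
                  band = tmpl@band, roiLabels = tmpl@roiLabels)
}

#' Node strength (weighted degree)
#'
#' Mean connectivity of each ROI with all other ROIs: the row mean of the
#' adjacency matrix excluding the diagonal.
#'
#' @param A an [AdjacencyMatrix-class] (or plain symmetric matrix).
#' @return named numeric K-vector in `[0, 1]`.
#' @export
nodeStrength <- function(A) {
  lab <- NULL
  if (is(A, "AdjacencyMatrix")) { lab <- A@roiLabels; A <- A@values }
  K <- nrow(A)
  if (K < 2) stop("need at least 2 ROIs")
  s <- (rowSums(A) - diag(A)) / (K - 1)
  if (!is.null(lab)) names(s) <- lab
  s
}

#' Binary degree after proportional thresholding
#'
#' Keeps edges at or above `fraction` times the maximum off-diagonal entry
#' and counts surviving edges per node. Invariant to global rescaling of
#' the matrix.
#'
#' @param A an [AdjacencyMatrix-class] (or plain matrix).
#' @param fraction threshold as a fraction of the maximum edge (default
#'   0.20).
#' @return named integer K-vector of degrees.
#' @export
degreeThresholded <- function(A, fraction = 0.20) {
  lab <- NULL
  if (is(A, "AdjacencyMatrix")) { lab <- A@roiLabels; A <- A@values }
  off <- A[row(A) != col(A)]
  m <- max(off)
  if (m <= 0) stop("all-zero adjacency matrix cannot be thresholded")
  B <- (A >= fraction * m) & (row(A) != col(A))
  d <- as.integer(rowSums(B))
  if (!is.null(lab)) names(d) <- lab
  d
}
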