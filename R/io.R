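## Plain-text file formats: sensor geometry and parcellation tables (TSV),
## recording matrices with a JSON sidecar, adjacency matrices, results.
## Numeric columns are written as %.17g (shortest exact representation of a
## double), so every writer/reader pair round-trips bit-for-bit.

.writeTSV <- function(d, path, col.names = TRUE) {
  for (j in seq_along(d))
    if (is.double(d[[j]])) d[[j]] <- sprintf("%.17g", d[[j]])
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
  invisible(path)
}

#' Read and write sensor geometry tables
#'
#' TSV with columns `id, x, y, z, ox, oy, oz` (positions in metres, unit
#' orientations). Orientations off unit norm by more than 1e-6 are
#' renormalised with a warning.
#'
#' @param path file path.
#' @return a [SensorArray-class].
#' @export
readSensors <- function(path) {
  d <- data.table::fread(path, sep = "\t", data.table = FALSE)
  need <- c("id", "x", "y", "z", "ox", "oy", "oz")
  if (!all(need %in% names(d)))
    stop("sensors file must have columns: ", paste(need, collapse = ", "))
  ori <- as.matrix(d[, c("ox", "oy", "oz")])
  nrm <- sqrt(rowSums(ori^2))
  bad <- abs(nrm - 1) > 1e-6
  if (any(bad)) {
    warning(sprintf("%d sensor orientation(s) renormalised to unit length",
                    sum(bad)))
    ori[bad, ] <- ori[bad, , drop = FALSE] / nrm[bad]
  }
  sensorArray(d$id, as.matrix(d[, c("x", "y", "z")]), ori)
}

#' @param sensors a [SensorArray-class].
#' @rdname readSensors
#' @export
writeSensors <- function(sensors, path) {
  d <- data.frame(id = sensors@ids,
                  x = sensors@positions[, 1], y = sensors@positions[, 2],
                  z = sensors@positions[, 3],
                  ox = sensors@orientations[, 1],
                  oy = sensors@orientations[, 2],
                  oz = sensors@orientations[, 3])
  .writeTSV(d, path)
}

#' Read and write parcellation tables
#'
#' TSV with columns `voxel_id, x_mm, y_mm, z_mm, roi_label` (positions in
#' millimetres on disk, metres in memory).
#'
#' @param path file path.
#' @return a [Parcellation-class].
#' @export
readParcellation <- function(path) {
  d <- data.table::fread(path, sep = "\t", data.table = FALSE)
  need <- c("voxel_id", "x_mm", "y_mm", "z_mm", "roi_label")
  if (!all(need %in% names(d)))
    stop("parcellation file must have columns: ", paste(need, collapse = ", "))
  parcellation(d$voxel_id,
               as.matrix(d[, c("x_mm", "y_mm", "z_mm")]) / 1000,
               d$roi_label)
}

#' @param parcel a [Parcellation-class].
#' @rdname readParcellation
#' @export
writeParcellation <- function(parcel, path) {
  d <- data.frame(voxel_id = parcel@voxelIds,
                  x_mm = parcel@positions[, 1] * 1000,
                  y_mm = parcel@positions[, 2] * 1000,
                  z_mm = parcel@positions[, 3] * 1000,
                  roi_label = parcel@voxelLabels)
  .writeTSV(d, path)
}

#' Read and write recording containers
#'
#' A recording is stored as `<prefix>.tsv` (channels x samples matrix, no
#' header) plus a JSON sidecar `<prefix>.json` holding `fs_hz`,
#' `channel_ids` and `units` ("T").
#'
#' @param prefix path prefix (without extension).
#' @return a [SensorRecording-class].
#' @export
readRecording <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  m <- as.matrix(data.table::fread(paste0(prefix, ".tsv"), sep = "\t",
                                   header = FALSE, data.table = FALSE))
  if (nrow(m) != length(side$channel_ids))
    stop(sprintf("recording shape mismatch: matrix has %d rows, sidecar lists %d channels",
                 nrow(m), length(side$channel_ids)))
  sensorRecording(m, side$fs_hz, side$channel_ids)
}

#' @param recording a [SensorRecording-class].
#' @rdname readRecording
#' @export
writeRecording <- function(recording, prefix) {
  .writeTSV(as.data.frame(recording@data), paste0(prefix, ".tsv"),
            col.names = FALSE)
  jsonlite::write_json(list(fs_hz = recording@fs,
                            channel_ids = recording@channelIds,
                            units = "T"),
                       paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read and write adjacency matrices
#'
#' TSV with ROI labels as header row and first column, plus a JSON sidecar
#' `<path>.json` recording estimator, band and aggregation level.
#'
#' @param path file path for the TSV (`<path>.json` is the sidecar).
#' @return an [AdjacencyMatrix-class].
#' @export
readAdjacency <- function(path) {
  d <- data.table::fread(path, sep = "\t", data.table = FALSE)
  lab <- d[[1]]
  m <- as.matrix(d[, -1, drop = FALSE])
  dimnames(m) <- NULL
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  adjacencyMatrix(m, side$estimator, level = side$level, band = side$band,
                  roiLabels = lab)
}

#' @param A an [AdjacencyMatrix-class].
#' @rdname readAdjacency
#' @export
writeAdjacency <- function(A, path) {
  d <- data.frame(roi = A@roiLabels, A@values)
  names(d) <- c("roi", A@roiLabels)
  .writeTSV(d, path)
  jsonlite::write_json(list(estimator = A@estimator, band = A@band,
                            level = A@level),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
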