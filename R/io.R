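# Plain-text I/O: CSV matrices with JSON sidecars for maps, recordings and
# slow series, plus optional NIfTI export of 2-D maps.

#' Write a spatial map as CSV with a JSON sidecar
#'
#' @param map A [spatial_map()].
#' @param path Output CSV path; metadata goes to `<path>.json`.
#' @return The CSV path, invisibly.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "spatial_map"))
  utils::write.table(map$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(c(list(resolution_mm = map$resolution_mm), map$meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a spatial map written by [write_map_csv()]
#' @param path CSV path (sidecar `<path>.json` must exist).
#' @return A [spatial_map()].
#' @export
read_map_csv <- function(path) {
  vals <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(vals) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  res <- meta$resolution_mm
  meta$resolution_mm <- NULL
  spatial_map(vals, res, meta = meta)
}

#' Write a multichannel recording as CSV with a JSON sidecar
#'
#' Channels are rows in row-major grid order; the sidecar records sampling
#' rate and grid geometry.
#'
#' @param recording A [multichannel_recording()].
#' @param path Output CSV path.
#' @return The CSV path, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "multichannel_recording"))
  utils::write.table(recording$data, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  g <- recording$geometry
  side <- list(fs = recording$fs, n_rows = g$n_rows, n_cols = g$n_cols,
               spacing_mm = g$spacing_mm)
  if (!is.null(recording$band)) side$band <- unclass(recording$band)
  jsonlite::write_json(c(side, recording$meta), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a recording written by [write_recording_csv()]
#' @param path CSV path.
#' @return A [multichannel_recording()].
#' @export
read_recording_csv <- function(path) {
  dat <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(dat) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  band <- if (length(meta$band) >= 3L) {
    frequency_band(meta$band$name, meta$band$f_low, meta$band$f_high)
  }
  multichannel_recording(dat, meta$fs,
                         grid_geometry(meta$n_rows, meta$n_cols,
                                       meta$spacing_mm),
                         band = band,
                         meta = meta[setdiff(names(meta),
                                             c("fs", "n_rows", "n_cols",
                                               "spacing_mm", "band"))])
}

#' Write a slow volume series as CSV (one column per voxel/ROI)
#'
#' @param series A [volume_series()].
#' @param path Output CSV path (header row of labels; sidecar JSON holds
#'   the volume interval and geometry).
#' @return The CSV path, invisibly.
#' @export
write_volume_series_csv <- function(series, path) {
  stopifnot(inherits(series, "volume_series"))
  dat <- series$data
  colnames(dat) <- series$labels %||% paste0("v", seq_len(ncol(dat)))
  utils::write.csv(dat, path, row.names = FALSE)
  g <- series$geometry
  jsonlite::write_json(
    c(list(volume_interval_s = series$volume_interval_s,
           n_rows = if (!is.null(g)) g$n_rows,
           n_cols = if (!is.null(g)) g$n_cols,
           spacing_mm = if (!is.null(g)) g$spacing_mm),
      series$meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a windowed-connectivity series (and optional states) as CSV
#'
#' @param wc A [windowed_connectivity()].
#' @param path Output CSV path.
#' @param states Optional `state_sequence` aligned with `wc`.
#' @return The CSV path, invisibly.
#' @export
write_windowed_csv <- function(wc, path, states = NULL) {
  stopifnot(inherits(wc, "windowed_connectivity"))
  d <- data.frame(window_start_s = wc$times, value = wc$values)
  if (!is.null(states)) d$state <- states$states
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Export a spatial map as NIfTI
#'
#' Writes the map as a single-slice NIfTI volume with pixel dimensions in
#' mm (requires the RNifti package).
#'
#' @param map A [spatial_map()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return The path, invisibly.
#' @export
write_map_nifti <- function(map, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("RNifti is required for NIfTI export", call. = FALSE)
  }
  arr <- array(t(map$values), dim = c(ncol(map$values), nrow(map$values), 1))
  img <- RNifti::asNifti(arr, pixdim = c(map$resolution_mm,
                                         map$resolution_mm, 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}
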