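# S3 containers shared across the package.

#' Electrode / voxel grid geometry
#'
#' Rectangular recording grid in physical units. Coordinates are row-major
#' with the origin at the top-left site; x runs along columns, y along rows,
#' both in millimetres.
#'
#' @param n_rows,n_cols Grid dimensions (counts, at least 1).
#' @param spacing_mm Inter-site spacing in mm (positive).
#' @return A `grid_geometry` object.
#' @examples
#' grid_geometry(7, 7, 0.4)  # a 7 x 7 microelectrode array at 400 um pitch
#' @export
grid_geometry <- function(n_rows, n_cols, spacing_mm) {
  if (n_rows < 1 || n_cols < 1) {
    stop("`n_rows` and `n_cols` must be at least 1", call. = FALSE)
  }
  check_positive(spacing_mm, "spacing_mm")
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         spacing_mm = spacing_mm),
    class = "grid_geometry"
  )
}

# x/y coordinates (mm) of every site, row-major order.
grid_coords <- function(geometry) {
  rows <- rep(seq_len(geometry$n_rows), each = geometry$n_cols)
  cols <- rep(seq_len(geometry$n_cols), times = geometry$n_rows)
  cbind(x = (cols - 1) * geometry$spacing_mm,
        y = (rows - 1) * geometry$spacing_mm)
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d sites, %.3g mm spacing\n",
              x$n_rows, x$n_cols, x$spacing_mm))
  invisible(x)
}

#' Multichannel recording
#'
#' Fast (electrophysiology-like) multichannel time series on a grid.
#'
#' @param data Numeric matrix, channels x samples, channels in row-major
#'   grid order.
#' @param fs Sampling rate in Hz.
#' @param geometry A [grid_geometry()].
#' @param band Optional [frequency_band()] the data is restricted to.
#' @param meta Optional list of provenance metadata.
#' @return A `multichannel_recording`.
#' @export
multichannel_recording <- function(data, fs, geometry, band = NULL,
                                   meta = list()) {
  check_positive(fs, "fs")
  data <- as.matrix(data)
  if (nrow(data) != geometry$n_rows * geometry$n_cols) {
    stop("`data` must have one row per grid site", call. = FALSE)
  }
  structure(
    list(data = data, fs = fs, geometry = geometry, band = band, meta = meta),
    class = "multichannel_recording"
  )
}

#' @export
print.multichannel_recording <- function(x, ...) {
  cat(sprintf("<multichannel_recording> %d ch x %d samples @ %g Hz (%.1f s)%s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              if (!is.null(x$band)) paste0(", band ", x$band$name) else ""))
  invisible(x)
}

#' Slow volume-sampled series
#'
#' Slow (hemodynamic-like) time series sampled once per imaging volume, one
#' column per voxel/ROI.
#'
#' @param data Numeric matrix, samples x voxels.
#' @param volume_interval_s Time between volumes, seconds.
#' @param geometry Optional [grid_geometry()] when the columns form a voxel
#'   grid (row-major order).
#' @param labels Optional character vector of region labels, one per column.
#' @param meta Optional metadata list.
#' @return A `volume_series`.
#' @export
volume_series <- function(data, volume_interval_s, geometry = NULL,
                          labels = NULL, meta = list()) {
  check_positive(volume_interval_s, "volume_interval_s")
  data <- as.matrix(data)
  if (!is.null(labels) && length(labels) != ncol(data)) {
    stop("`labels` must have one entry per column", call. = FALSE)
  }
  structure(
    list(data = data, volume_interval_s = volume_interval_s,
         geometry = geometry, labels = labels, meta = meta),
    class = "volume_series"
  )
}

#' @export
print.volume_series <- function(x, ...) {
  cat(sprintf("<volume_series> %d volumes x %d voxels @ %g s/volume\n",
              nrow(x$data), ncol(x$data), x$volume_interval_s))
  invisible(x)
}

#' 2-D scalar field with physical resolution
#'
#' @param values Numeric matrix (rows = y, cols = x, origin top-left).
#' @param resolution_mm Pixel size in mm.
#' @param meta Optional metadata list (e.g. ground-truth parameters).
#' @return A `spatial_map`.
#' @export
spatial_map <- function(values, resolution_mm, meta = list()) {
  check_positive(resolution_mm, "resolution_mm")
  structure(
    list(values = as.matrix(values), resolution_mm = resolution_mm,
         meta = meta),
    class = "spatial_map"
  )
}

#' @export
print.spatial_map <- function(x, ...) {
  cat(sprintf("<spatial_map> %d x %d px @ %.3g mm, range [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values), x$resolution_mm,
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

# Coordinate vectors (mm) of a spatial map's pixel centres.
map_axes <- function(map) {
  list(x = (seq_len(ncol(map$values)) - 1) * map$resolution_mm,
       y = (seq_len(nrow(map$values)) - 1) * map$resolution_mm)
}

#' Windowed connectivity series
#'
#' Per-window connectivity scalars from a sliding-window analysis.
#'
#' @param values Numeric vector, one connectivity value per window (NA where
#'   a window was degenerate).
#' @param window_s,step_s Window length and step, seconds.
#' @param measure One of `"pearson_r"`, `"band_msc"`, `"blp_r"`.
#' @param band Optional [frequency_band()].
#' @param times Window start times, seconds (computed if missing).
#' @return A `windowed_connectivity`.
#' @export
windowed_connectivity <- function(values, window_s, step_s,
                                  measure = c("pearson_r", "band_msc", "blp_r"),
                                  band = NULL, times = NULL) {
  measure <- match.arg(measure)
  check_positive(window_s, "window_s")
  check_positive(step_s, "step_s")
  if (is.null(times)) times <- (seq_along(values) - 1) * step_s
  structure(
    list(values = as.numeric(values), window_s = window_s, step_s = step_s,
         measure = measure, band = band, times = times),
    class = "windowed_connectivity"
  )
}

#' @export
print.windowed_connectivity <- function(x, ...) {
  cat(sprintf("<windowed_connectivity> %d windows (%g s window, %g s step), %s%s\n",
              length(x$values), x$window_s, x$step_s, x$measure,
              if (!is.null(x$band)) paste0(" [", x$band$name, "]") else ""))
  invisible(x)
}
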