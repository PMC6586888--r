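# Minimal slow-signal preparation: 0.01-0.1 Hz zero-phase band filtering,
# block-averaged percent-signal-change activation maps with argmax seed
# selection, and seed-based correlation maps.

#' Zero-phase slow band-pass (0.01-0.1 Hz)
#'
#' Band-passes each voxel series between `f_low` and `f_high` with the
#' package's zero-phase second-order Chebyshev filter. The conventional
#' resting-state corner pair 0.01-0.1 Hz is the default; DC and drifts fall
#' below `f_low` and are removed.
#'
#' @param series A [volume_series()] spanning at least `2 / f_low` seconds.
#' @param f_low,f_high Corner frequencies, Hz.
#' @return A filtered [volume_series()].
#' @export
bandpass_slow <- function(series, f_low = 0.01, f_high = 0.1) {
  stopifnot(inherits(series, "volume_series"))
  fs <- 1 / series$volume_interval_s
  dur <- nrow(series$data) * series$volume_interval_s
  if (dur < 2 / f_low) {
    stop(sprintf("series spans %.3g s; need at least %.3g s for f_low = %g Hz",
                 dur, 2 / f_low, f_low), call. = FALSE)
  }
  band <- frequency_band("slow", f_low, f_high)
  flt <- cheby_bandpass(band, fs)
  pad <- as.integer(3 * ceiling(fs / f_low))
  out <- apply(series$data, 2L, zero_phase_filter, flt = flt, pad = pad)
  meta <- series$meta
  meta$filtered_hz <- c(f_low, f_high)
  meta$preprocessing <- c(meta$preprocessing,
                          "bandpass 0.01-0.1 Hz (zero phase)")
  volume_series(out, series$volume_interval_s, geometry = series$geometry,
                labels = series$labels, meta = meta)
}

#' Block-averaged percent-signal-change activation map
#'
#' Per voxel, the percent signal change between each on-block (10 volumes
#' at a 3 s volume interval for a 30 s block) and its pre-stimulus baseline
#' (the last 7 of the 10 volumes preceding onset), averaged over blocks,
#' then normalized region-wise to a maximum of 1. The voxel attaining each
#' region's maximum is selected as that region's seed.
#'
#' @param series A [volume_series()] with grid geometry.
#' @param paradigm A [stimulus_paradigm()] (leading-off convention, see
#'   [generate_block_design_series()]).
#' @param n_on_volumes Volumes per on-block used (default 10).
#' @param n_pre_volumes Baseline volumes used, taken as the last of the 10
#'   volumes before onset (default 7).
#' @return An `activation_result`: `map` (a [spatial_map()], region-wise max
#'   1) and `seeds` (named list of voxel indices, column order of the
#'   series).
#' @export
percent_change_map <- function(series, paradigm, n_on_volumes = 10,
                               n_pre_volumes = 7) {
  stopifnot(inherits(series, "volume_series"),
            inherits(paradigm, "stimulus_paradigm"))
  dt <- series$volume_interval_s
  n_vol <- nrow(series$data)
  onsets <- block_onsets(paradigm, n_vol * dt)
  onset_vol <- round(onsets / dt) + 1L  # first volume of each on-block
  change <- vapply(seq_len(ncol(series$data)), function(vx) {
    x <- series$data[, vx]
    per_block <- vapply(onset_vol, function(v0) {
      on_idx <- v0:(v0 + n_on_volumes - 1L)
      pre_idx <- (v0 - n_pre_volumes):(v0 - 1L)
      if (max(on_idx) > n_vol || min(pre_idx) < 1L) return(NA_real_)
      pre <- mean(x[pre_idx])
      if (pre == 0) return(NA_real_)
      100 * (mean(x[on_idx]) - pre) / pre
    }, numeric(1))
    mean(per_block, na.rm = TRUE)
  }, numeric(1))
  labels <- series$labels %||% rep("all", ncol(series$data))
  normed <- change
  seeds <- list()
  for (rg in unique(labels)) {
    idx <- which(labels == rg)
    mx <- max(change[idx], na.rm = TRUE)
    if (is.finite(mx) && mx != 0) normed[idx] <- change[idx] / mx
    seeds[[rg]] <- idx[which.max(change[idx])]
  }
  g <- series$geometry
  map <- if (!is.null(g)) {
    spatial_map(matrix(normed, nrow = g$n_rows, ncol = g$n_cols, byrow = TRUE),
                g$spacing_mm,
                meta = list(measure = "percent_change_normalized"))
  } else {
    spatial_map(matrix(normed, nrow = 1L), 1,
                meta = list(measure = "percent_change_normalized"))
  }
  structure(list(map = map, seeds = seeds, raw_percent_change = change),
            class = "activation_result")
}

#' Seed-based correlation map of a slow series
#'
#' Pearson correlation of each voxel's series with the seed voxel's series,
#' arranged on the grid; the seed's own value is 1, zero-variance voxels
#' are NA.
#'
#' @param series A [volume_series()] with grid geometry.
#' @param seed Voxel index (column of the series, row-major grid order).
#' @return A `seed_map` [spatial_map()] with `meta$seed_index`.
#' @export
seed_correlation_map <- function(series, seed) {
  stopifnot(inherits(series, "volume_series"))
  n_vx <- ncol(series$data)
  if (seed < 1L || seed > n_vx) stop("`seed` outside the grid", call. = FALSE)
  xs <- series$data[, seed]
  if (stats::sd(xs) == 0) stop("seed voxel has zero variance", call. = FALSE)
  vals <- vapply(seq_len(n_vx), function(vx) {
    if (vx == seed) return(1)
    if (stats::sd(series$data[, vx]) == 0) return(NA_real_)
    stats::cor(xs, series$data[, vx])
  }, numeric(1))
  g <- series$geometry
  if (is.null(g)) stop("series has no grid geometry", call. = FALSE)
  spatial_map(matrix(vals, nrow = g$n_rows, ncol = g$n_cols, byrow = TRUE),
              g$spacing_mm,
              meta = list(seed_index = seed, measure = "pearson_r"))
}
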