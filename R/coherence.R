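# Welch magnitude-squared coherence, band-averaged coherence scalars,
# seed-to-all coherence maps, and stimulus-evoked power-change maps.

#' Welch magnitude-squared coherence between two series
#'
#' Estimates MSC(f) = |Sxy|^2 / (Sxx Syy) with Hann-windowed, mean-removed
#' overlapping segments. With a single segment the estimate is identically 1,
#' so at least two segments are required. Zero-variance input is flagged as
#' missing (all-NA spectrum), not coerced to 0.
#'
#' @param x,y Equal-length numeric series.
#' @param fs Sampling rate, Hz.
#' @param segment_s Welch segment length, seconds (default 2).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return A `coherence_spectrum` with `freqs`, `msc` (in `[0, 1]` up to
#'   floating error, clipped at 1e-12 excess) and `n_averages`.
#' @export
msc <- function(x, y, fs, segment_s = 2, overlap = 0.5) {
  if (length(x) != length(y)) stop("series must have equal length", call. = FALSE)
  check_positive(fs, "fs")
  nseg <- round(segment_s * fs)
  if (nseg < 4L) stop("`segment_s` too short", call. = FALSE)
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  if (length(starts) < 2L) {
    stop("need at least 2 Welch segments; lengthen the series or shorten `segment_s`",
         call. = FALSE)
  }
  nf <- nseg %/% 2L + 1L
  freqs <- (seq_len(nf) - 1L) * fs / nseg
  degenerate <- stats::var(x) == 0 || stats::var(y) == 0
  if (degenerate) {
    return(structure(list(freqs = freqs, msc = rep(NA_real_, nf),
                          n_averages = length(starts), missing = TRUE),
                     class = "coherence_spectrum"))
  }
  w <- hann_window(nseg)
  segmat <- function(z) {
    m <- vapply(starts, function(s) {
      seg <- z[s:(s + nseg - 1L)]
      (seg - mean(seg)) * w
    }, numeric(nseg))
    stats::mvfft(m)[seq_len(nf), , drop = FALSE]
  }
  X <- segmat(x)
  Y <- segmat(y)
  # auto-spectra through the same summation path as the cross-spectrum so
  # that msc(x, x) is exactly 1
  Sxx <- Re(rowMeans(X * Conj(X)))
  Syy <- Re(rowMeans(Y * Conj(Y)))
  Sxy <- rowMeans(X * Conj(Y))
  den <- Sxx * Syy
  coh <- rep(NA_real_, nf)
  ok <- den > 0
  coh[ok] <- (Re(Sxy[ok])^2 + Im(Sxy[ok])^2) / den[ok]
  over <- ok & coh > 1 & coh <= 1 + 1e-12
  coh[over] <- 1
  structure(list(freqs = freqs, msc = coh, n_averages = length(starts),
                 missing = FALSE),
            class = "coherence_spectrum")
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf("<coherence_spectrum> %d bins to %.4g Hz, %d averages\n",
              length(x$freqs), max(x$freqs), x$n_averages))
  invisible(x)
}

#' Band-averaged coherence scalar
#'
#' Mean MSC over the frequency bins falling inside a band (inclusive edges).
#' This scalar is the per-band coherence statistic used everywhere
#' downstream.
#'
#' @param spec A `coherence_spectrum` from [msc()].
#' @param band A [frequency_band()].
#' @return Scalar in `[0, 1]` (NA when the spectrum is flagged missing).
#' @export
band_average_msc <- function(spec, band) {
  stopifnot(inherits(spec, "coherence_spectrum"),
            inherits(band, "frequency_band"))
  idx <- spec$freqs >= band$f_low & spec$freqs <= band$f_high
  if (!any(idx)) {
    stop(sprintf("band %s (%g-%g Hz) overlaps no frequency bin",
                 band$name, band$f_low, band$f_high), call. = FALSE)
  }
  mean(spec$msc[idx])
}

#' Seed-to-all band coherence map
#'
#' Band-averaged MSC between one seed channel and every channel of a grid
#' recording, arranged on the grid. The seed's own entry is 1 by definition;
#' dead (zero-variance) channels are NA.
#'
#' @param recording A [multichannel_recording()].
#' @param seed Channel index (row-major grid order).
#' @param band A [frequency_band()].
#' @param segment_s,overlap Welch parameters passed to [msc()].
#' @return A `seed_map`: a [spatial_map()] with `meta$seed_index`.
#' @export
seed_coherence_map <- function(recording, seed, band,
                               segment_s = 2, overlap = 0.5) {
  g <- recording$geometry
  n_ch <- nrow(recording$data)
  if (seed < 1L || seed > n_ch) stop("`seed` outside the grid", call. = FALSE)
  xs <- recording$data[seed, ]
  vals <- vapply(seq_len(n_ch), function(ch) {
    if (ch == seed) return(1)
    if (stats::var(recording$data[ch, ]) == 0) return(NA_real_)
    band_average_msc(msc(xs, recording$data[ch, ], recording$fs,
                         segment_s = segment_s, overlap = overlap), band)
  }, numeric(1))
  m <- matrix(vals, nrow = g$n_rows, ncol = g$n_cols, byrow = TRUE)
  spatial_map(m, g$spacing_mm,
              meta = list(seed_index = seed, band = band$name,
                          measure = "band_msc",
                          n_averages = msc(xs, xs, recording$fs, segment_s,
                                           overlap)$n_averages))
}

# On/off block onset times (s). Runs start with a leading off (baseline)
# period of `block_off_s`, then alternate on/off.
block_onsets <- function(paradigm, total_s) {
  onsets <- paradigm$block_off_s +
    (seq_len(paradigm$n_blocks) - 1) * (paradigm$block_on_s + paradigm$block_off_s)
  onsets[onsets + paradigm$block_on_s <= total_s + 1e-9]
}

#' Stimulus-evoked band power-change map
#'
#' Per channel, the percentage change in band power between the steady-state
#' stimulus period and the immediately preceding baseline:
#' `100 * (P_stim - P_pre) / P_pre`, averaged over blocks, then normalized to
#' the map maximum for the run. Following the convention that onset
#' transients bias steady-state power, the first `stim_skip_s` seconds of
#' each on-block are excluded; `P_pre` uses the final `pre_window_s` seconds
#' of the preceding off period.
#'
#' @param recording A [multichannel_recording()] (raw; filtered internally).
#' @param paradigm A [stimulus_paradigm()].
#' @param band A [frequency_band()].
#' @param stim_skip_s Seconds of each on-block discarded after onset
#'   (default 10, leaving seconds 10-30 of a 30 s block).
#' @param pre_window_s Baseline window length before each onset (default 20).
#' @param normalize Normalize the map to its maximum (default TRUE).
#' @return A [spatial_map()]; channels with zero baseline power are NA.
#' @export
stimulus_power_change_map <- function(recording, paradigm, band,
                                      stim_skip_s = 10, pre_window_s = 20,
                                      normalize = TRUE) {
  g <- recording$geometry
  fs <- recording$fs
  total_s <- ncol(recording$data) / fs
  onsets <- block_onsets(paradigm, total_s)
  if (length(onsets) == 0L) stop("no complete stimulus block in the recording",
                                 call. = FALSE)
  filtered <- bandpass(recording, band)
  change <- vapply(seq_len(nrow(filtered$data)), function(ch) {
    x <- filtered$data[ch, ]
    per_block <- vapply(onsets, function(t0) {
      stim_idx <- seq(round((t0 + stim_skip_s) * fs) + 1L,
                      round((t0 + paradigm$block_on_s) * fs))
      pre_idx <- seq(round((t0 - pre_window_s) * fs) + 1L, round(t0 * fs))
      p_stim <- mean(x[stim_idx]^2)
      p_pre <- mean(x[pre_idx]^2)
      if (p_pre == 0) return(NA_real_)
      100 * (p_stim - p_pre) / p_pre
    }, numeric(1))
    mean(per_block)
  }, numeric(1))
  m <- matrix(change, nrow = g$n_rows, ncol = g$n_cols, byrow = TRUE)
  if (normalize) {
    mx <- max(m, na.rm = TRUE)
    if (is.finite(mx) && mx != 0) m <- m / mx
  }
  spatial_map(m, g$spacing_mm,
              meta = list(band = band$name, measure = "power_change_pct",
                          normalized = normalize, n_blocks = length(onsets)))
}
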