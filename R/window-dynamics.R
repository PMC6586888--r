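# Sliding-window connectivity for slow (Pearson r) and fast (band-averaged
# coherence) series, Fisher z transformation, and discretization of windowed
# connectivity into putative brain states.

# Window start indices for a series of n samples.
window_starts <- function(n, wlen, step) {
  if (wlen > n) stop("window longer than the series", call. = FALSE)
  seq(1L, n - wlen + 1L, by = step)
}

#' Sliding-window Pearson correlation
#'
#' Pearson r between two equal-length series in a window of `window_s`
#' seconds shifted by `step_s`; window k covers
#' `[k step, k step + window_s)`. The number of windows is
#' `floor((T - window_s)/step_s) + 1`. Zero-variance windows yield NA
#' (propagated, not dropped).
#'
#' @param a,b Equal-length numeric series.
#' @param sample_interval_s Time between samples, seconds.
#' @param window_s Window length, seconds (at least 3 samples).
#' @param step_s Step, seconds (default 3, one imaging volume).
#' @return A [windowed_connectivity()] with measure `"pearson_r"`.
#' @export
sliding_correlation <- function(a, b, sample_interval_s, window_s = 60,
                                step_s = 3) {
  if (length(a) != length(b)) stop("series must have equal length", call. = FALSE)
  wlen <- round(window_s / sample_interval_s)
  step <- max(1L, round(step_s / sample_interval_s))
  if (wlen < 3L) stop("window must span at least 3 samples", call. = FALSE)
  starts <- window_starts(length(a), wlen, step)
  vals <- vapply(starts, function(s) {
    ai <- a[s:(s + wlen - 1L)]
    bi <- b[s:(s + wlen - 1L)]
    if (stats::sd(ai) == 0 || stats::sd(bi) == 0) return(NA_real_)
    stats::cor(ai, bi)
  }, numeric(1))
  windowed_connectivity(vals, window_s, step_s, measure = "pearson_r",
                        times = (starts - 1L) * sample_interval_s)
}

#' Sliding-window band-averaged coherence
#'
#' Band-averaged Welch MSC ([msc()] then [band_average_msc()]) recomputed in
#' a sliding window, the fast-modality counterpart of
#' [sliding_correlation()]. The window must hold at least two Welch
#' segments.
#'
#' @param x,y Equal-length fast series.
#' @param fs Sampling rate, Hz.
#' @param band A [frequency_band()].
#' @param window_s,step_s Window length and step, seconds.
#' @param segment_s,overlap Welch parameters within each window.
#' @return A [windowed_connectivity()] with measure `"band_msc"`.
#' @export
sliding_band_coherence <- function(x, y, fs, band, window_s = 60, step_s = 3,
                                   segment_s = 2, overlap = 0.5) {
  if (length(x) != length(y)) stop("series must have equal length", call. = FALSE)
  wlen <- round(window_s * fs)
  step <- max(1L, round(step_s * fs))
  starts <- window_starts(length(x), wlen, step)
  vals <- vapply(starts, function(s) {
    idx <- s:(s + wlen - 1L)
    sp <- msc(x[idx], y[idx], fs, segment_s = segment_s, overlap = overlap)
    if (isTRUE(sp$missing)) return(NA_real_)
    band_average_msc(sp, band)
  }, numeric(1))
  windowed_connectivity(vals, window_s, step_s, measure = "band_msc",
                        band = band, times = (starts - 1L) / fs)
}

#' Fisher z transform
#'
#' `z = arctanh(r)`; correlations of exactly +/-1 are clipped to
#' `+/-(1 - 1e-7)` first so the transform stays finite.
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @return z value(s).
#' @seealso [inverse_fisher_z()]
#' @export
fisher_z <- function(r) {
  r <- pmin(1 - 1e-7, pmax(-1 + 1e-7, r))
  atanh(r)
}

#' Inverse Fisher z transform
#' @param z z value(s).
#' @return Correlation value(s), `tanh(z)`.
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Discretize windowed connectivity into brain states
#'
#' Clamps values to `domain` then assigns them to `n_states` equal half-open
#' bins `[edge_k, edge_{k+1})` (last bin closed), so the domain endpoints
#' map to states 1 and `n_states`. Missing values stay missing and are
#' excluded from jump counting; their count is recorded.
#'
#' @param values Numeric vector, or a [windowed_connectivity()].
#' @param n_states Number of states (default 50).
#' @param domain Binning domain `c(lo, hi)`. Defaults by measure:
#'   `[-1, 1]` for correlation-based measures, `[0, 1]` for coherence.
#' @param on For correlation measures: bin the correlations themselves
#'   (`"r"`, default — the bounded scale matching the `[-1, 1]` domain) or
#'   Fisher z clipped to the domain (`"z_clipped"`, sensitivity variant).
#' @return A `state_sequence` with fields `states`, `n_states`, `domain`,
#'   `n_missing`.
#' @export
bin_states <- function(values, n_states = 50, domain = NULL,
                       on = c("r", "z_clipped")) {
  on <- match.arg(on)
  measure <- NULL
  if (inherits(values, "windowed_connectivity")) {
    measure <- values$measure
    values <- values$values
  }
  if (is.null(domain)) {
    domain <- if (identical(measure, "band_msc")) c(0, 1) else c(-1, 1)
  }
  lo <- domain[1]; hi <- domain[2]
  if (!(lo < hi)) stop("`domain` must satisfy lo < hi", call. = FALSE)
  if (on == "z_clipped" && !identical(measure, "band_msc")) {
    values <- pmin(hi, pmax(lo, fisher_z(values)))
  }
  v <- pmin(hi, pmax(lo, values))
  width <- (hi - lo) / n_states
  states <- ifelse(is.na(v), NA_integer_,
                   pmin(n_states, floor((v - lo) / width) + 1L))
  structure(
    list(states = as.integer(states), n_states = as.integer(n_states),
         domain = c(lo, hi), n_missing = sum(is.na(states))),
    class = "state_sequence"
  )
}

#' @export
print.state_sequence <- function(x, ...) {
  cat(sprintf("<state_sequence> %d steps over %d states on [%g, %g] (%d missing)\n",
              length(x$states), x$n_states, x$domain[1], x$domain[2],
              x$n_missing))
  invisible(x)
}
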