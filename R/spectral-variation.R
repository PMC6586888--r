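# Fourier decomposition of windowed-connectivity fluctuations: how fast
# does connectivity vary, summarized as the percentage of spectral power in
# five slow fluctuation-frequency bands.

# Default fluctuation-band edges (Hz); bands are left-closed/right-open,
# the top band extends to the windowed-series Nyquist.
variation_band_edges <- c(0.0025, 0.005, 0.01, 0.02)
variation_band_labels <- c("<0.0025", "0.0025-0.005", "0.005-0.01",
                           "0.01-0.02", ">0.02")

#' Fourier spectrum of connectivity fluctuations
#'
#' Raw (untapered) periodogram of the mean-removed windowed-connectivity
#' series, normalized to percentages of total non-DC power, with cumulative
#' fractions over five fluctuation bands: below 0.0025 Hz, 0.0025-0.005,
#' 0.005-0.01, 0.01-0.02, and above 0.02 Hz (to the Nyquist of the windowed
#' series, `1/(2 step)`). Frequency resolution is `1/(N step)`. The
#' periodogram satisfies Parseval: total power equals the population
#' variance of the mean-removed series.
#'
#' @param wc A [windowed_connectivity()] with at least 16 windows, uniform
#'   step, no missing values.
#' @param taper Optional taper: `"none"` (default) or `"hann"`.
#' @return A `variation_spectrum` with `freqs`, `power`, `percent` (sums to
#'   100) and `cumulative_bands` (named, sums to 100).
#' @export
variation_spectrum <- function(wc, taper = c("none", "hann")) {
  stopifnot(inherits(wc, "windowed_connectivity"))
  taper <- match.arg(taper)
  v <- wc$values
  if (anyNA(v)) stop("windowed series contains missing values", call. = FALSE)
  n <- length(v)
  if (n < 16L) stop("need at least 16 windows", call. = FALSE)
  if (length(unique(round(diff(wc$times), 9))) > 1L) {
    stop("window step is not uniform", call. = FALSE)
  }
  dt <- wc$step_s
  x <- v - mean(v)
  if (taper == "hann") {
    w <- hann_window(n)
    x <- x * w / sqrt(mean(w^2))
  }
  X <- stats::fft(x)
  nf <- n %/% 2L
  k <- seq_len(nf)
  power <- Mod(X[k + 1L])^2 / n^2
  # fold the negative-frequency half (Nyquist bin of an even series is unpaired)
  unpaired_nyquist <- (n %% 2L == 0L)
  dbl <- if (unpaired_nyquist) k < nf else rep(TRUE, nf)
  power[dbl] <- 2 * power[dbl]
  freqs <- k / (n * dt)
  total <- sum(power)
  percent <- 100 * power / total
  band_idx <- findInterval(freqs, variation_band_edges) + 1L
  cum <- vapply(seq_along(variation_band_labels),
                function(i) sum(percent[band_idx == i]), numeric(1))
  names(cum) <- variation_band_labels
  structure(
    list(freqs = freqs, power = power, percent = percent,
         cumulative_bands = cum, resolution_hz = 1 / (n * dt),
         nyquist_hz = 1 / (2 * dt), taper = taper, n_windows = n),
    class = "variation_spectrum"
  )
}

#' @export
print.variation_spectrum <- function(x, ...) {
  cat(sprintf("<variation_spectrum> %d bins, df = %.4g Hz\n",
              length(x$freqs), x$resolution_hz))
  print(round(x$cumulative_bands, 2))
  invisible(x)
}

#' Paired comparison of fluctuation-band fractions across conditions
#'
#' For every pair of conditions and every fluctuation band, a paired
#' Wilcoxon signed-rank test (via [wilcoxon_paired()]) across runs on the
#' per-run cumulative band percentages.
#'
#' @param spectra_by_condition Named list; each element a list of
#'   `variation_spectrum` objects, one per run, runs paired across
#'   conditions (equal lengths, at least 2 runs).
#' @return Data frame: `condition_a`, `condition_b`, `band`, `mean_a`,
#'   `mean_b`, `statistic`, `p_value`, `degenerate`.
#' @export
compare_band_variation <- function(spectra_by_condition) {
  conds <- names(spectra_by_condition)
  if (length(conds) < 2L) stop("need at least two conditions", call. = FALSE)
  n_runs <- lengths(spectra_by_condition)
  if (length(unique(n_runs)) != 1L) {
    stop("conditions have unpaired run counts", call. = FALSE)
  }
  if (n_runs[1L] < 2L) {
    stop("insufficient n: need at least 2 paired runs", call. = FALSE)
  }
  frac <- lapply(spectra_by_condition, function(lst) {
    t(vapply(lst, function(sp) sp$cumulative_bands,
             numeric(length(variation_band_labels))))
  })
  out <- list()
  for (i in seq_len(length(conds) - 1L)) {
    for (j in (i + 1L):length(conds)) {
      for (b in variation_band_labels) {
        a_vals <- frac[[conds[i]]][, b]
        b_vals <- frac[[conds[j]]][, b]
        w <- wilcoxon_paired(a_vals, b_vals)
        out[[length(out) + 1L]] <- data.frame(
          condition_a = conds[i], condition_b = conds[j], band = b,
          mean_a = mean(a_vals), mean_b = mean(b_vals),
          statistic = w$statistic, p_value = w$p_value,
          degenerate = w$degenerate)
      }
    }
  }
  do.call(rbind, out)
}
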