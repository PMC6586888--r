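# Frequency-band decomposition of fast multichannel signals: zero-phase
# Chebyshev band-pass filtering, trial-averaged dB spectrograms, and
# band-limited power (BLP) envelopes.

#' Frequency band definition
#'
#' @param name Band label.
#' @param f_low,f_high Band edges in Hz, `0 < f_low < f_high`.
#' @return A `frequency_band`.
#' @export
frequency_band <- function(name, f_low, f_high) {
  check_positive(f_low, "f_low")
  check_positive(f_high, "f_high")
  if (f_low >= f_high) stop("`f_low` must be below `f_high`", call. = FALSE)
  structure(list(name = as.character(name), f_low = f_low, f_high = f_high),
            class = "frequency_band")
}

#' @export
print.frequency_band <- function(x, ...) {
  cat(sprintf("<frequency_band> %s: %g-%g Hz\n", x$name, x$f_low, x$f_high))
  invisible(x)
}

#' Canonical LFP frequency bands
#'
#' The eight bands conventionally used to partition local field potential
#' oscillations: delta (1-4 Hz), theta (5-8), alpha (9-14), beta (15-30),
#' gamma low (30-50), gamma high (50-100), gamma very high (100-150) and
#' broad band (1-150).
#'
#' @param names Optional subset of band names to return.
#' @return A named list of [frequency_band()] objects.
#' @export
lfp_bands <- function(names = NULL) {
  tbl <- list(
    delta           = frequency_band("delta", 1, 4),
    theta           = frequency_band("theta", 5, 8),
    alpha           = frequency_band("alpha", 9, 14),
    beta            = frequency_band("beta", 15, 30),
    gamma_low       = frequency_band("gamma_low", 30, 50),
    gamma_high      = frequency_band("gamma_high", 50, 100),
    gamma_very_high = frequency_band("gamma_very_high", 100, 150),
    broad           = frequency_band("broad", 1, 150)
  )
  if (is.null(names)) return(tbl)
  missing <- setdiff(names, base::names(tbl))
  if (length(missing)) {
    stop("unknown band name(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tbl[names]
}

# Design the order-2 Chebyshev type-1 band-pass used throughout.
cheby_bandpass <- function(band, fs, ripple_db = 0.5) {
  nyq <- fs / 2
  if (band$f_high >= nyq) {
    stop(sprintf("band edge %g Hz is at or above Nyquist (%g Hz)",
                 band$f_high, nyq), call. = FALSE)
  }
  signal::cheby1(2, ripple_db, c(band$f_low, band$f_high) / nyq, type = "pass")
}

# Zero-phase filtering of one channel with reflect padding.
zero_phase_filter <- function(x, flt, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  xp <- reflect_pad(x, pad)
  y <- signal::filtfilt(flt, xp)
  y[(pad + 1L):(pad + n)]
}

#' Zero-phase band-pass filtering of a recording
#'
#' Applies a second-order Chebyshev type-1 band-pass forward and backward
#' (zero phase; effective stopband attenuation is squared). Edges are handled
#' by reflect-padding each channel by three low-edge periods before
#' filtering; the padded span is recorded in the output metadata.
#'
#' @param recording A [multichannel_recording()].
#' @param band A [frequency_band()] with `f_high` below Nyquist.
#' @param ripple_db Passband ripple in dB (default 0.5).
#' @return A band-restricted [multichannel_recording()] of identical length.
#' @export
bandpass <- function(recording, band, ripple_db = 0.5) {
  stopifnot(inherits(recording, "multichannel_recording"),
            inherits(band, "frequency_band"))
  flt <- cheby_bandpass(band, recording$fs, ripple_db)
  pad <- as.integer(3 * ceiling(recording$fs / band$f_low))
  if (ncol(recording$data) <= 3L) {
    stop("recording too short to filter", call. = FALSE)
  }
  out <- t(apply(recording$data, 1L, zero_phase_filter, flt = flt, pad = pad))
  meta <- recording$meta
  meta$edge_padded_s <- min(pad, ncol(recording$data) - 1L) / recording$fs
  multichannel_recording(out, recording$fs, recording$geometry,
                         band = band, meta = meta)
}

#' Trial-averaged spectrogram on a decibel scale
#'
#' Short-time Fourier power of one channel, Hann-windowed, optionally
#' averaged across equal-length trials, then converted to dB (10 log10).
#' Power is normalized so that summing a column over frequency recovers the
#' windowed signal's mean power (Parseval).
#'
#' @param x Numeric vector, or a [multichannel_recording()] plus `channel`.
#' @param fs Sampling rate (ignored when `x` is a recording).
#' @param channel Channel index when `x` is a recording.
#' @param window_s STFT window length, seconds (`window_s * fs >= 8`).
#' @param overlap Fractional overlap between windows in `[0, 1)`.
#' @param trial_s Optional trial length (s); power is averaged across trials.
#' @param db_floor Floor (dB) substituted for zero-power cells so the dB map
#'   stays finite.
#' @return A `spectrogram` with `times`, `freqs`, `power`, `power_db`.
#' @export
spectrogram_db <- function(x, fs = NULL, channel = 1L, window_s = 1,
                           overlap = 0.5, trial_s = NULL, db_floor = -120) {
  if (inherits(x, "multichannel_recording")) {
    fs <- x$fs
    x <- x$data[channel, ]
  }
  check_positive(fs, "fs")
  nwin <- round(window_s * fs)
  if (nwin < 8L) stop("`window_s` must cover at least 8 samples", call. = FALSE)
  ntrial <- if (is.null(trial_s)) length(x) else round(trial_s * fs)
  n_trials <- length(x) %/% ntrial
  if (n_trials < 1L) stop("series shorter than one trial", call. = FALSE)

  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, ntrial - nwin + 1L, by = step)
  w <- hann_window(nwin)
  scale <- sum(w^2)  # Parseval normalization for the Hann taper
  nf <- nwin %/% 2L + 1L
  acc <- matrix(0, nrow = nf, ncol = length(starts))
  for (tr in seq_len(n_trials)) {
    off <- (tr - 1L) * ntrial
    seg <- vapply(starts, function(s) x[(off + s):(off + s + nwin - 1L)] * w,
                  numeric(nwin))
    X <- stats::mvfft(seg)
    P <- Mod(X[seq_len(nf), , drop = FALSE])^2 / (scale * nwin)
    # fold negative frequencies into the one-sided spectrum
    if (nwin %% 2L == 0L) {
      P[2L:(nf - 1L), ] <- 2 * P[2L:(nf - 1L), ]
    } else {
      P[2L:nf, ] <- 2 * P[2L:nf, ]
    }
    acc <- acc + P
  }
  power <- acc / n_trials
  power_db <- 10 * log10(pmax(power, 10^(db_floor / 10)))
  structure(
    list(times = (starts - 1L + nwin / 2) / fs,
         freqs = (seq_len(nf) - 1L) * fs / nwin,
         power = power, power_db = power_db, n_trials = n_trials,
         db_floor = db_floor),
    class = "spectrogram"
  )
}

#' Band-limited power envelope
#'
#' Band-passes a recording and extracts the slow power envelope of each
#' channel: the analytic-signal magnitude (default) or a rectify-and-smooth
#' alternative, optionally low-pass smoothed by a centred moving average.
#'
#' @param recording A [multichannel_recording()].
#' @param band A [frequency_band()].
#' @param smoothing_s Smoothing window in seconds; spans shorter than one
#'   sample are treated as no smoothing.
#' @param method `"hilbert"` (analytic signal) or `"rectify"`.
#' @return A [multichannel_recording()] of nonnegative envelopes.
#' @export
band_limited_power <- function(recording, band, smoothing_s = 0,
                               method = c("hilbert", "rectify")) {
  method <- match.arg(method)
  filtered <- bandpass(recording, band)
  env <- t(apply(filtered$data, 1L, function(ch) {
    if (method == "hilbert") analytic_envelope(ch) else abs(ch)
  }))
  k <- round(smoothing_s * recording$fs)
  if (k >= 2L) {
    if (k %% 2L == 0L) k <- k + 1L
    kern <- rep(1 / k, k)
    env <- t(apply(env, 1L, function(ch) {
      sm <- stats::filter(ch, kern, sides = 2)
      # fill filter edges with shrinking one-sided means
      idx <- which(is.na(sm))
      half <- (k - 1L) %/% 2L
      n <- length(ch)
      for (i in idx) {
        lo <- max(1L, i - half); hi <- min(n, i + half)
        sm[i] <- mean(ch[lo:hi])
      }
      as.numeric(sm)
    }))
  }
  meta <- filtered$meta
  meta$blp_method <- method
  meta$blp_smoothing_s <- smoothing_s
  multichannel_recording(pmax(env, 0), recording$fs, recording$geometry,
                         band = band, meta = meta)
}
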