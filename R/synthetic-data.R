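# Synthetic-data generators: electrode-grid recordings with calibrated
# distance-dependent coherence, Markov-switching coupled signal pairs shared
# between a slow (hemodynamic-like) and a fast (LFP-like) modality,
# elliptical activation blobs, and block-design stimulus series.

#' Markov coupling-state model
#'
#' A discrete-time Markov chain over coupling strengths. The hidden state
#' holds for `dwell_s` seconds, then moves according to `transition_matrix`;
#' the next state depends only on the present one.
#'
#' @param states Numeric vector of coupling strengths in `[-1, 1]`.
#' @param transition_matrix Row-stochastic square matrix (rows sum to 1
#'   within 1e-12), one row per state.
#' @param dwell_s Dwell step duration in seconds.
#' @return A `coupling_state_model`.
#' @export
coupling_state_model <- function(states, transition_matrix, dwell_s) {
  states <- as.numeric(states)
  if (any(abs(states) > 1)) {
    stop("coupling strengths must lie in [-1, 1]", call. = FALSE)
  }
  tm <- as.matrix(transition_matrix)
  if (nrow(tm) != ncol(tm) || nrow(tm) != length(states)) {
    stop("`transition_matrix` must be square with one row per state",
         call. = FALSE)
  }
  if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-12)) {
    stop("`transition_matrix` rows must be nonnegative and sum to 1",
         call. = FALSE)
  }
  check_positive(dwell_s, "dwell_s")
  structure(list(states = states, transition_matrix = tm, dwell_s = dwell_s),
            class = "coupling_state_model")
}

#' Default coupling-state model
#'
#' Five coupling levels spanning `[-0.9, 0.9]` with a reflecting
#' nearest-neighbour random walk (stay probability 0.5) and a 30 s dwell
#' step, i.e. a state change roughly once per minute — slow enough for a
#' 60 s analysis window to track, fast enough to produce many transitions
#' in a 15 min run.
#'
#' @param dwell_s Dwell step (s), default 30.
#' @param stay Probability of remaining in the current state per step.
#' @return A [coupling_state_model()].
#' @export
default_coupling_model <- function(dwell_s = 30, stay = 0.5) {
  states <- c(-0.9, -0.45, 0, 0.45, 0.9)
  k <- length(states)
  tm <- matrix(0, k, k)
  move <- 1 - stay
  for (i in seq_len(k)) {
    tm[i, i] <- stay
    if (i == 1L) {
      tm[i, 2L] <- move
    } else if (i == k) {
      tm[i, k - 1L] <- move
    } else {
      tm[i, i - 1L] <- move / 2
      tm[i, i + 1L] <- move / 2
    }
  }
  coupling_state_model(states, tm, dwell_s)
}

#' Block-design stimulus paradigm
#'
#' On/off block structure: runs begin with one leading off (baseline) period
#' of `block_off_s`, followed by `n_blocks` repetitions of on then off.
#'
#' @param block_on_s,block_off_s Block durations, seconds.
#' @param n_blocks Number of on-blocks.
#' @param rate_hz Stimulus pulse rate within on-blocks (metadata).
#' @return A `stimulus_paradigm`.
#' @export
stimulus_paradigm <- function(block_on_s = 30, block_off_s = 30, n_blocks = 7,
                              rate_hz = 8) {
  for (nm in c("block_on_s", "block_off_s", "n_blocks", "rate_hz")) {
    check_positive(get(nm), nm)
  }
  structure(list(block_on_s = block_on_s, block_off_s = block_off_s,
                 n_blocks = as.integer(n_blocks), rate_hz = rate_hz),
            class = "stimulus_paradigm")
}

paradigm_duration_s <- function(paradigm) {
  paradigm$block_off_s +
    paradigm$n_blocks * (paradigm$block_on_s + paradigm$block_off_s)
}

# Gaussian source-mixing weights realizing a target coherence-vs-distance
# kernel. Channel i mixes a lattice of shared band-limited sources with
# Gaussian weights of width sigma_w = FWHM / (2 sqrt(2 ln 2)); for unit-norm
# weight rows the pairwise coherence equals the squared cosine between
# weight vectors, which for a dense lattice is exp(-4 ln 2 d^2 / FWHM^2) —
# a Gaussian in distance with the requested FWHM.
coherence_mixing_weights <- function(geometry, coherence_fwhm_mm) {
  coords <- grid_coords(geometry)
  n_ch <- nrow(coords)
  if (coherence_fwhm_mm <= 0) {
    return(list(W = diag(n_ch), n_sources = n_ch))
  }
  sigma_w <- coherence_fwhm_mm / (2 * sqrt(2 * log(2)))
  pad <- 3 * sigma_w
  pitch <- sigma_w / sqrt(2)
  gx <- seq(min(coords[, "x"]) - pad, max(coords[, "x"]) + pad, by = pitch)
  gy <- seq(min(coords[, "y"]) - pad, max(coords[, "y"]) + pad, by = pitch)
  src <- cbind(x = rep(gx, times = length(gy)), y = rep(gy, each = length(gx)))
  W <- exp(-(outer(coords[, "x"], src[, "x"], "-")^2 +
             outer(coords[, "y"], src[, "y"], "-")^2) / (2 * sigma_w^2))
  W <- W / sqrt(rowSums(W^2))
  list(W = W, n_sources = nrow(src))
}

#' Generate an electrode-grid recording with calibrated spatial coherence
#'
#' Each channel is a sum of band-limited Gaussian processes obtained by
#' mixing a dense lattice of shared latent sources with Gaussian
#' distance-dependent weights, so that the expected magnitude-squared
#' coherence between two channels in every band decays as a Gaussian of
#' their separation with the stated FWHM (identical channels at distance 0
#' give coherence 1; a zero-width kernel gives independent channels).
#'
#' @param geometry A [grid_geometry()].
#' @param duration_s Recording length, seconds.
#' @param fs Sampling rate (Hz); must be at least twice the highest band
#'   edge.
#' @param bands Named list of [frequency_band()]s (default [lfp_bands()]).
#' @param band_powers Named numeric vector of per-band variances (default 1
#'   for every band).
#' @param coherence_fwhm_mm FWHM (mm) of the coherence-vs-distance Gaussian.
#' @param seed RNG seed (mandatory; equal seeds give bit-identical output).
#' @return A [multichannel_recording()].
#' @export
generate_lfp_grid <- function(geometry, duration_s, fs, bands = lfp_bands(),
                              band_powers = NULL, coherence_fwhm_mm = 1.2,
                              seed) {
  check_positive(duration_s, "duration_s")
  check_positive(fs, "fs")
  f_top <- max(vapply(bands, function(b) b$f_high, numeric(1)))
  if (fs < 2 * f_top) {
    stop(sprintf("`fs` = %g Hz cannot represent a %g Hz band edge", fs, f_top),
         call. = FALSE)
  }
  if (is.null(band_powers)) {
    band_powers <- stats::setNames(rep(1, length(bands)), names(bands))
  }
  n <- round(duration_s * fs)
  mix <- coherence_mixing_weights(geometry, coherence_fwhm_mm)
  n_ch <- nrow(mix$W)
  with_seed(seed, {
    out <- matrix(0, nrow = n_ch, ncol = n)
    for (bn in names(bands)) {
      b <- bands[[bn]]
      src <- band_limited_noise(n, fs, b$f_low, b$f_high,
                                n_series = mix$n_sources)
      out <- out + sqrt(band_powers[[bn]]) * (mix$W %*% t(src))
    }
    multichannel_recording(out, fs, geometry,
                           meta = list(generator = "lfp_grid", seed = seed,
                                       coherence_fwhm_mm = coherence_fwhm_mm,
                                       band_powers = as.list(band_powers)))
  })
}

# Simulate the hidden state path; returns per-dwell-step state indices.
simulate_state_path <- function(model, n_steps) {
  k <- length(model$states)
  # start from the stationary distribution for a stationary path
  pi0 <- stationary_distribution(model$transition_matrix)
  path <- integer(n_steps)
  path[1L] <- sample.int(k, 1L, prob = pi0)
  for (t in seq_len(n_steps - 1L)) {
    path[t + 1L] <- sample.int(k, 1L, prob = model$transition_matrix[path[t], ])
  }
  path
}

stationary_distribution <- function(tm) {
  e <- eigen(t(tm))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# Fidelity rule: bands wholly at/below 15 Hz (and the broadband, which the
# low bands dominate) follow the path with `low`, bands wholly above with
# `high`.
band_fidelity <- function(band, low, high) {
  if (band$f_high <= 15) low else if (band$f_low >= 15) high else low
}

# Mix a shared component into two noise series with time-varying coupling c:
# x1 = sqrt(|c|) z + sqrt(1-|c|) e1, x2 = sign(c) sqrt(|c|) z + sqrt(1-|c|) e2
# gives instantaneous correlation c with unit variance throughout.
couple_pair <- function(z, e1, e2, c) {
  a <- sqrt(abs(c))
  b <- sqrt(1 - abs(c))
  list(x1 = a * z + b * e1,
       x2 = sign(c) * a * z + b * e2)
}

#' Generate a Markov-coupled slow/fast signal pair
#'
#' Realizes a hidden Markov coupling path and builds (a) a pair of slow
#' 0.01-0.1 Hz band-limited series sampled once per volume whose
#' instantaneous correlation tracks the path, and (b) a pair of fast
#' broadband channels whose band-specific coherence tracks a
#' fidelity-degraded copy of the same path: each band's effective coupling
#' is `c_bar + fidelity * (c(t) - c_bar)` about the chain's stationary mean
#' `c_bar`, with fidelity `low_band_fidelity` for bands at or below 15 Hz
#' (and the broadband) and `high_band_fidelity` for bands above. Fidelity 1
#' reproduces the path exactly; fidelity 0 freezes the band's coupling at
#' its mean so its connectivity carries no dynamics.
#'
#' @param model A [coupling_state_model()].
#' @param duration_s Run length, seconds.
#' @param fs_fast Fast sampling rate, Hz.
#' @param volume_interval_s Slow sampling interval, seconds; must be an
#'   integer multiple of `1/fs_fast`.
#' @param low_band_fidelity,high_band_fidelity Path fidelities in `[0, 1]`.
#' @param bands Named list of [frequency_band()]s for the fast pair.
#' @param slow_band Frequency range (Hz) of the slow signals.
#' @param seed RNG seed.
#' @return A list: `slow` ([volume_series()], 2 columns), `fast`
#'   ([multichannel_recording()], 2 channels), and `path` (data frame of
#'   per-volume `time_s`, `state`, `coupling`).
#' @export
generate_coupled_pair <- function(model = default_coupling_model(),
                                  duration_s = 900, fs_fast = 500,
                                  volume_interval_s = 3,
                                  low_band_fidelity = 1,
                                  high_band_fidelity = 0,
                                  bands = lfp_bands(),
                                  slow_band = c(0.01, 0.1), seed) {
  stopifnot(inherits(model, "coupling_state_model"))
  for (f in c(low_band_fidelity, high_band_fidelity)) {
    if (f < 0 || f > 1) stop("fidelities must lie in [0, 1]", call. = FALSE)
  }
  ratio <- volume_interval_s * fs_fast
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("`volume_interval_s` must be an integer multiple of 1/fs_fast",
         call. = FALSE)
  }
  n_fast <- round(duration_s * fs_fast)
  n_vol <- floor(duration_s / volume_interval_s)
  n_steps <- ceiling(duration_s / model$dwell_s)

  with_seed(seed, {
    path_steps <- simulate_state_path(model, n_steps)
    coupling_steps <- model$states[path_steps]
    step_of_fast <- pmin(n_steps,
                         floor((seq_len(n_fast) - 1) / (model$dwell_s * fs_fast)) + 1L)
    c_fast <- coupling_steps[step_of_fast]
    vol_t <- (seq_len(n_vol) - 1) * volume_interval_s
    step_of_vol <- pmin(n_steps, floor(vol_t / model$dwell_s) + 1L)
    c_vol <- coupling_steps[step_of_vol]

    # slow pair: band-limited components mixed with per-volume coupling
    zs <- band_limited_noise(n_vol, 1 / volume_interval_s,
                             slow_band[1], slow_band[2], n_series = 3L)
    slow <- couple_pair(zs[, 1], zs[, 2], zs[, 3], c_vol)

    # fast pair: per-band components with fidelity-scaled coupling paths
    c_bar <- sum(stationary_distribution(model$transition_matrix) * model$states)
    x1 <- numeric(n_fast)
    x2 <- numeric(n_fast)
    for (bn in names(bands)) {
      b <- bands[[bn]]
      fid <- band_fidelity(b, low_band_fidelity, high_band_fidelity)
      p_b <- pmin(1, pmax(-1, c_bar + fid * (c_fast - c_bar)))
      zb <- band_limited_noise(n_fast, fs_fast, b$f_low, b$f_high,
                               n_series = 3L)
      pair <- couple_pair(zb[, 1], zb[, 2], zb[, 3], p_b)
      x1 <- x1 + pair$x1
      x2 <- x2 + pair$x2
    }

    list(
      slow = volume_series(cbind(roi_a = slow$x1, roi_b = slow$x2),
                           volume_interval_s,
                           labels = c("roi_a", "roi_b"),
                           meta = list(generator = "coupled_pair", seed = seed,
                                       slow_band = slow_band)),
      fast = multichannel_recording(rbind(x1, x2), fs_fast,
                                    grid_geometry(1, 2, 1),
                                    meta = list(generator = "coupled_pair",
                                                seed = seed,
                                                low_band_fidelity = low_band_fidelity,
                                                high_band_fidelity = high_band_fidelity)),
      path = data.frame(time_s = vol_t, state = path_steps[step_of_vol],
                        coupling = c_vol)
    )
  })
}

#' Generate an elliptical Gaussian activation map
#'
#' Unit-peak elliptical Gaussian plus optional i.i.d. Gaussian noise. The
#' ground-truth parameters are stored in the map metadata (including the
#' implied FWHMs, `2 sqrt(2 ln 2) * sigma`).
#'
#' @param n_rows,n_cols Map dimensions in pixels.
#' @param resolution_mm Pixel size, mm.
#' @param center_mm Blob centre `(x, y)` in mm (default: map centre).
#' @param sigma_major_mm,sigma_minor_mm Gaussian widths (mm), positive.
#' @param orientation_rad Major-axis angle from the +x axis, radians.
#' @param noise_sd Noise standard deviation (0 for a clean map).
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @return A [spatial_map()] with truth parameters in `meta`.
#' @export
generate_activation_map <- function(n_rows, n_cols, resolution_mm = 0.1,
                                    center_mm = NULL, sigma_major_mm,
                                    sigma_minor_mm, orientation_rad = 0,
                                    noise_sd = 0, seed = NULL) {
  check_positive(sigma_major_mm, "sigma_major_mm")
  check_positive(sigma_minor_mm, "sigma_minor_mm")
  if (is.null(center_mm)) {
    center_mm <- c((n_cols - 1) / 2, (n_rows - 1) / 2) * resolution_mm
  }
  xs <- (seq_len(n_cols) - 1) * resolution_mm
  ys <- (seq_len(n_rows) - 1) * resolution_mm
  dx <- outer(rep(1, n_rows), xs - center_mm[1])
  dy <- outer(ys - center_mm[2], rep(1, n_cols))
  u <- cos(orientation_rad) * dx + sin(orientation_rad) * dy
  v <- -sin(orientation_rad) * dx + cos(orientation_rad) * dy
  vals <- exp(-(u^2 / (2 * sigma_major_mm^2) + v^2 / (2 * sigma_minor_mm^2)))
  if (noise_sd > 0) {
    if (is.null(seed)) stop("`seed` is required when `noise_sd` > 0",
                            call. = FALSE)
    vals <- vals + with_seed(seed, matrix(stats::rnorm(n_rows * n_cols,
                                                       sd = noise_sd),
                                          n_rows, n_cols))
  }
  fwhm <- 2 * sqrt(2 * log(2))
  spatial_map(vals, resolution_mm,
              meta = list(generator = "activation_map",
                          center_mm = center_mm,
                          sigma_major_mm = sigma_major_mm,
                          sigma_minor_mm = sigma_minor_mm,
                          fwhm_major_mm = fwhm * sigma_major_mm,
                          fwhm_minor_mm = fwhm * sigma_minor_mm,
                          orientation_rad = orientation_rad,
                          noise_sd = noise_sd, seed = seed))
}

#' Generate a block-design stimulus-response series
#'
#' Builds a run following a [stimulus_paradigm()] whose per-site response
#' amplitude is proportional to a response map. Two modes:
#'
#' * slow mode (`volume_interval_s` given): additive mean response —
#'   `baseline + amplitude * map * boxcar + noise`, a [volume_series()];
#' * fast mode (`fs` given): variance-modulated band-limited carrier noise,
#'   `sqrt(1 + amplitude * map * boxcar) * carrier`, so the *band power*
#'   rises by `amplitude * map` during on-blocks, a
#'   [multichannel_recording()].
#'
#' @param paradigm A [stimulus_paradigm()].
#' @param response_map A [spatial_map()]; its pixels define the sites
#'   (row-major) and per-site response gains.
#' @param volume_interval_s Slow sampling interval (s), or `NULL`.
#' @param fs Fast sampling rate (Hz), or `NULL`. Exactly one of
#'   `volume_interval_s` / `fs` must be given.
#' @param carrier_band [frequency_band()] of the fast carrier noise.
#' @param baseline Slow-mode baseline level (default 100).
#' @param amplitude Peak response amplitude (slow mode: same units as
#'   `baseline`; fast mode: fractional power increase at the map peak).
#' @param noise_sd Additive noise SD (slow mode only).
#' @param seed RNG seed.
#' @return A [volume_series()] or [multichannel_recording()].
#' @export
generate_block_design_series <- function(paradigm, response_map,
                                         volume_interval_s = NULL, fs = NULL,
                                         carrier_band = NULL, baseline = 100,
                                         amplitude = 1, noise_sd = 0, seed) {
  stopifnot(inherits(paradigm, "stimulus_paradigm"),
            inherits(response_map, "spatial_map"))
  if (is.null(volume_interval_s) == is.null(fs)) {
    stop("give exactly one of `volume_interval_s` (slow) or `fs` (fast)",
         call. = FALSE)
  }
  total_s <- paradigm_duration_s(paradigm)
  gains <- as.numeric(t(response_map$values))  # row-major site order
  n_site <- length(gains)
  geometry <- grid_geometry(nrow(response_map$values),
                            ncol(response_map$values),
                            response_map$resolution_mm)
  if (!is.null(volume_interval_s)) {
    n <- round(total_s / volume_interval_s)
    t_s <- (seq_len(n) - 1) * volume_interval_s
    box <- as.numeric(stimulus_boxcar(paradigm, t_s))
    with_seed(seed, {
      noise <- if (noise_sd > 0) {
        matrix(stats::rnorm(n * n_site, sd = noise_sd), n, n_site)
      } else 0
      dat <- baseline + outer(box, gains) * amplitude + noise
      volume_series(dat, volume_interval_s, geometry = geometry,
                    meta = list(generator = "block_design", seed = seed,
                                baseline = baseline, amplitude = amplitude,
                                paradigm = unclass(paradigm)))
    })
  } else {
    if (is.null(carrier_band)) {
      stop("`carrier_band` is required in fast mode", call. = FALSE)
    }
    n <- round(total_s * fs)
    t_s <- (seq_len(n) - 1) / fs
    box <- as.numeric(stimulus_boxcar(paradigm, t_s))
    with_seed(seed, {
      dat <- matrix(0, n_site, n)
      for (ch in seq_len(n_site)) {
        carrier <- band_limited_noise(n, fs, carrier_band$f_low,
                                      carrier_band$f_high)
        dat[ch, ] <- sqrt(pmax(0, 1 + amplitude * gains[ch] * box)) * carrier
      }
      multichannel_recording(dat, fs, geometry, band = carrier_band,
                             meta = list(generator = "block_design",
                                         seed = seed, amplitude = amplitude,
                                         paradigm = unclass(paradigm)))
    })
  }
}

# 1 during on-blocks, 0 otherwise, for times t_s (seconds).
stimulus_boxcar <- function(paradigm, t_s) {
  cycle <- paradigm$block_on_s + paradigm$block_off_s
  rel <- t_s - paradigm$block_off_s
  in_cycles <- rel >= 0 & rel < paradigm$n_blocks * cycle
  phase <- rel %% cycle
  in_cycles & phase < paradigm$block_on_s
}
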