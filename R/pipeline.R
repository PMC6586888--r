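# End-to-end session orchestration: configuration, the generate -> filter ->
# connect -> window -> compare chain, per-band spatial-extent sessions, and
# group-level paired Wilcoxon inference.

#' Per-band spatial-extent (PSF) session parameters
#'
#' Ground-truth spatial kernels for the synthetic spatial-extent analysis:
#' resting-state coherence-vs-distance FWHMs and stimulus-response blob
#' FWHMs per band (mm). Defaults emulate the mesoscale finding that low
#' bands have spatially broad resting coherence but compact stimulus
#' responses, while the 50-150 Hz bands show the reverse.
#'
#' @param rest_fwhm_mm,stim_fwhm_mm Named numeric vectors (per band), mm.
#' @param geometry Electrode grid (default 7 x 7 at 0.4 mm).
#' @param rest_duration_s Resting recording length per band, seconds.
#' @param fs Sampling rate for the per-band recordings, Hz.
#' @param stim_amplitude Fractional band-power increase at the blob peak.
#' @param n_stim_blocks On-blocks per stimulus run.
#' @return A list of PSF-session settings.
#' @export
psf_session_config <- function(
    rest_fwhm_mm = c(delta = 1.8, theta = 1.8, alpha = 1.7, beta = 1.6,
                     gamma_low = 1.2, gamma_high = 0.9,
                     gamma_very_high = 0.8, broad = 1.7),
    stim_fwhm_mm = c(delta = 1.0, theta = 1.0, alpha = 1.0, beta = 1.1,
                     gamma_low = 1.3, gamma_high = 1.5,
                     gamma_very_high = 1.5, broad = 1.3),
    geometry = grid_geometry(7, 7, 0.4),
    rest_duration_s = 120, fs = 500,
    stim_amplitude = 3, n_stim_blocks = 4) {
  list(rest_fwhm_mm = rest_fwhm_mm, stim_fwhm_mm = stim_fwhm_mm,
       geometry = geometry, rest_duration_s = rest_duration_s, fs = fs,
       stim_amplitude = stim_amplitude, n_stim_blocks = n_stim_blocks)
}

#' Session configuration
#'
#' Validated configuration for one synthetic session. Every free parameter
#' of the downstream analyses is set here and serialized alongside outputs.
#'
#' @param seed RNG seed for the session (mandatory).
#' @param duration_s,fs,volume_interval_s Run length and sampling of the
#'   coupled-pair generator.
#' @param bands Named list of [frequency_band()]s to analyse.
#' @param window_s,step_s Sliding-window parameters (60 s / 3 s defaults).
#' @param n_states State count for discretization (default 50).
#' @param model [coupling_state_model()] for the hidden coupling path.
#' @param low_band_fidelity,high_band_fidelity Path fidelities.
#' @param segment_s,overlap Welch parameters.
#' @param blp_smoothing_s Envelope smoothing for the BLP route, seconds.
#' @param psf A [psf_session_config()].
#' @param stages Subset of `c("dynamics", "psf")`.
#' @param out_dir Optional directory for CSV/JSON artifacts.
#' @return A validated `run_config`.
#' @export
session_config <- function(seed, duration_s = 900, fs = 500,
                           volume_interval_s = 3, bands = lfp_bands(),
                           window_s = 60, step_s = 3, n_states = 50,
                           model = default_coupling_model(),
                           low_band_fidelity = 1, high_band_fidelity = 0,
                           segment_s = 2, overlap = 0.5,
                           blp_smoothing_s = 0,
                           psf = psf_session_config(),
                           stages = c("dynamics", "psf"),
                           out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), duration_s = duration_s, fs = fs,
              volume_interval_s = volume_interval_s, bands = bands,
              window_s = window_s, step_s = step_s,
              n_states = as.integer(n_states), model = model,
              low_band_fidelity = low_band_fidelity,
              high_band_fidelity = high_band_fidelity,
              segment_s = segment_s, overlap = overlap,
              blp_smoothing_s = blp_smoothing_s, psf = psf,
              stages = match.arg(stages, c("dynamics", "psf"),
                                 several.ok = TRUE),
              out_dir = out_dir)
  validate_session_config(cfg)
  structure(cfg, class = "run_config")
}

validate_session_config <- function(cfg) {
  for (nm in c("duration_s", "fs", "volume_interval_s", "window_s", "step_s",
               "segment_s")) {
    check_positive(cfg[[nm]], nm)
  }
  if (cfg$n_states < 2L) stop("`n_states` must be at least 2", call. = FALSE)
  if (!all(vapply(cfg$bands, inherits, logical(1), "frequency_band"))) {
    stop("`bands` must be a list of frequency_band objects", call. = FALSE)
  }
  stopifnot(inherits(cfg$model, "coupling_state_model"))
  for (f in c(cfg$low_band_fidelity, cfg$high_band_fidelity)) {
    if (f < 0 || f > 1) stop("fidelities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$window_s < 2 * cfg$segment_s) {
    stop("`window_s` must hold at least two Welch segments", call. = FALSE)
  }
  invisible(cfg)
}

# JSON-serializable view of a config (for sidecars and the manifest hash).
config_as_list <- function(cfg) {
  list(seed = cfg$seed, duration_s = cfg$duration_s, fs = cfg$fs,
       volume_interval_s = cfg$volume_interval_s,
       bands = lapply(cfg$bands, function(b) unclass(b)),
       window_s = cfg$window_s, step_s = cfg$step_s,
       n_states = cfg$n_states,
       model = list(states = cfg$model$states,
                    transition_matrix = cfg$model$transition_matrix,
                    dwell_s = cfg$model$dwell_s),
       low_band_fidelity = cfg$low_band_fidelity,
       high_band_fidelity = cfg$high_band_fidelity,
       segment_s = cfg$segment_s, overlap = cfg$overlap,
       blp_smoothing_s = cfg$blp_smoothing_s,
       psf = list(rest_fwhm_mm = as.list(cfg$psf$rest_fwhm_mm),
                  stim_fwhm_mm = as.list(cfg$psf$stim_fwhm_mm),
                  rest_duration_s = cfg$psf$rest_duration_s,
                  fs = cfg$psf$fs,
                  stim_amplitude = cfg$psf$stim_amplitude,
                  n_stim_blocks = cfg$psf$n_stim_blocks),
       stages = cfg$stages)
}

#' Run one end-to-end synthetic session
#'
#' Executes the configured stages for one seeded run:
#'
#' * `dynamics` — generate a Markov-coupled slow/fast pair; sliding-window
#'   Pearson correlation of the slow pair (with Fisher z recorded) and
#'   per-band sliding-window coherence and BLP-envelope correlation of the
#'   fast pair; discretize every windowed series into brain states; jump
#'   ECDFs and per-band K-S statistics against the slow modality; per-band
#'   fluctuation spectra.
#' * `psf` — per band, a resting electrode-grid recording with the
#'   configured coherence kernel and a stimulus run with the configured
#'   response blob; seed coherence maps and power-change maps; elliptical
#'   PSF fits and half-maximum areas for both conditions.
#'
#' Re-running with an identical config yields identical tables; when
#' `out_dir` is set, all tables, the serialized config and an artifact
#' manifest are written there (deterministically, no timestamps).
#'
#' @param config A [session_config()].
#' @return A list: `table` (tidy data frame of `run_id`, `condition`,
#'   `band`, `metric`, `value`) plus stage detail objects (`dynamics`,
#'   `psf`).
#' @export
run_session <- function(config) {
  stopifnot(inherits(config, "run_config"))
  run_id <- sprintf("run_%06d", config$seed)
  rows <- list()
  details <- list()
  add <- function(condition, band, metric, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      run_id = run_id, condition = condition, band = band, metric = metric,
      value = value)
  }

  if ("dynamics" %in% config$stages) {
    t0 <- proc.time()["elapsed"]
    pair <- generate_coupled_pair(
      model = config$model, duration_s = config$duration_s,
      fs_fast = config$fs, volume_interval_s = config$volume_interval_s,
      low_band_fidelity = config$low_band_fidelity,
      high_band_fidelity = config$high_band_fidelity,
      bands = config$bands, seed = config$seed)

    slow_f <- bandpass_slow(pair$slow)
    wc_slow <- sliding_correlation(slow_f$data[, 1], slow_f$data[, 2],
                                   config$volume_interval_s,
                                   window_s = config$window_s,
                                   step_s = config$step_s)
    seq_slow <- bin_states(wc_slow, n_states = config$n_states)
    spec_slow <- variation_spectrum(wc_slow)
    add("rest", "slow", "windowed_r_mean", mean(wc_slow$values, na.rm = TRUE))
    for (b in names(spec_slow$cumulative_bands)) {
      add("rest", "slow", paste0("variation_pct_", b),
          spec_slow$cumulative_bands[[b]])
    }

    coh_seqs <- list()
    blp_seqs <- list()
    wc_bands <- list()
    for (bn in names(config$bands)) {
      band <- config$bands[[bn]]
      wc_coh <- sliding_band_coherence(
        pair$fast$data[1, ], pair$fast$data[2, ], config$fs, band,
        window_s = config$window_s, step_s = config$step_s,
        segment_s = config$segment_s, overlap = config$overlap)
      coh_seqs[[bn]] <- bin_states(wc_coh, n_states = config$n_states)
      env <- band_limited_power(pair$fast, band,
                                smoothing_s = config$blp_smoothing_s)
      wc_blp <- sliding_correlation(env$data[1, ], env$data[2, ],
                                    1 / config$fs,
                                    window_s = config$window_s,
                                    step_s = config$step_s)
      blp_seqs[[bn]] <- bin_states(wc_blp, n_states = config$n_states)
      wc_bands[[bn]] <- list(coherence = wc_coh, blp = wc_blp)
      add("rest", bn, "windowed_msc_mean", mean(wc_coh$values, na.rm = TRUE))
      spec_b <- variation_spectrum(wc_coh)
      for (vb in names(spec_b$cumulative_bands)) {
        add("rest", bn, paste0("variation_pct_", vb),
            spec_b$cumulative_bands[[vb]])
      }
    }

    ks_coh <- ks_band_profile(seq_slow, coh_seqs, measure = "coherence")
    ks_blp <- ks_band_profile(seq_slow, blp_seqs, measure = "blp")
    for (i in seq_len(nrow(ks_coh))) {
      add("rest", ks_coh$band[i], "ks_coherence", ks_coh$ks_statistic[i])
    }
    for (i in seq_len(nrow(ks_blp))) {
      add("rest", ks_blp$band[i], "ks_blp", ks_blp$ks_statistic[i])
    }
    details$dynamics <- list(pair_path = pair$path, wc_slow = wc_slow,
                             wc_bands = wc_bands, seq_slow = seq_slow,
                             coh_seqs = coh_seqs, blp_seqs = blp_seqs,
                             ks = rbind(ks_coh, ks_blp))
    message(sprintf("[%s] dynamics stage: %.1f s", run_id,
                    proc.time()["elapsed"] - t0))
  }

  if ("psf" %in% config$stages) {
    t0 <- proc.time()["elapsed"]
    psf <- config$psf
    g <- psf$geometry
    center_ch <- (g$n_rows %/% 2) * g$n_cols + g$n_cols %/% 2 + 1L
    fits <- list()
    for (bn in names(config$bands)) {
      band <- config$bands[[bn]]
      if (band$f_high >= psf$fs / 2) {
        stop(sprintf("psf stage: band %s needs fs > %g Hz", bn,
                     2 * band$f_high), call. = FALSE)
      }
      rest_rec <- generate_lfp_grid(
        g, psf$rest_duration_s, psf$fs,
        bands = config$bands[bn],
        coherence_fwhm_mm = psf$rest_fwhm_mm[[bn]],
        seed = config$seed * 101L + match(bn, names(config$bands)))
      rest_map <- seed_coherence_map(rest_rec, center_ch, band,
                                     segment_s = config$segment_s,
                                     overlap = config$overlap)
      rest_fit <- fit_elliptical_psf(rest_map)

      blob <- generate_activation_map(
        g$n_rows, g$n_cols, resolution_mm = g$spacing_mm,
        sigma_major_mm = psf$stim_fwhm_mm[[bn]] / (2 * sqrt(2 * log(2))),
        sigma_minor_mm = psf$stim_fwhm_mm[[bn]] / (2 * sqrt(2 * log(2))))
      paradigm <- stimulus_paradigm(n_blocks = psf$n_stim_blocks)
      stim_rec <- generate_block_design_series(
        paradigm, blob, fs = psf$fs, carrier_band = band,
        amplitude = psf$stim_amplitude,
        seed = config$seed * 101L + 50L + match(bn, names(config$bands)))
      stim_map <- stimulus_power_change_map(stim_rec, paradigm, band)
      stim_fit <- fit_elliptical_psf(stim_map)

      add("rest", bn, "psf_area_mm2", rest_fit$area_mm2)
      add("rest", bn, "psf_fwhm_major_mm", rest_fit$fwhm_major_mm)
      add("stim", bn, "psf_area_mm2", stim_fit$area_mm2)
      add("stim", bn, "psf_fwhm_major_mm", stim_fit$fwhm_major_mm)
      fits[[bn]] <- list(rest = rest_fit, stim = stim_fit)
    }
    details$psf <- fits
    message(sprintf("[%s] psf stage: %.1f s", run_id,
                    proc.time()["elapsed"] - t0))
  }

  table <- do.call(rbind, rows)
  result <- c(list(table = table, run_id = run_id, config = config), details)
  if (!is.null(config$out_dir)) write_session_artifacts(result, config)
  result
}

write_session_artifacts <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  path <- function(name) file.path(config$out_dir,
                                   paste0(result$run_id, "_", name))
  tab_file <- path("table.csv")
  utils::write.csv(result$table, tab_file, row.names = FALSE)
  files <- c(files, tab_file)
  if (!is.null(result$dynamics)) {
    wc <- result$dynamics$wc_slow
    wcd <- data.frame(window_start_s = wc$times, value = wc$values,
                      state = result$dynamics$seq_slow$states)
    f <- path("windowed_slow.csv")
    utils::write.csv(wcd, f, row.names = FALSE)
    files <- c(files, f)
    f <- path("ks.csv")
    utils::write.csv(result$dynamics$ks, f, row.names = FALSE)
    files <- c(files, f)
  }
  cfg_file <- path("config.json")
  jsonlite::write_json(config_as_list(config), cfg_file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, cfg_file)
  manifest <- list(run_id = result$run_id,
                   artifacts = basename(files),
                   config_digest = digest_config(config))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(files)
}

# Stable content digest of a config (sum of serialized bytes; enough to
# detect accidental config drift between artifacts without extra deps).
digest_config <- function(config) {
  raw <- serialize(config_as_list(config), NULL, version = 2)
  sprintf("%08x-%d", sum(as.integer(raw)) %% 0xFFFFFFF, length(raw))
}

#' Run a group of sessions
#'
#' Runs [run_session()] for `n_runs` seeds derived from `base_seed`
#' (mirroring a design of several runs across a few animals) and stacks the
#' tidy tables.
#'
#' @param config Template [session_config()]; its seed is replaced per run.
#' @param n_runs Number of runs (default 9).
#' @param base_seed Base RNG seed; run k uses `base_seed + k`.
#' @return A list with `table` (stacked group table) and `runs` (list of
#'   per-run results).
#' @export
run_group <- function(config, n_runs = 9, base_seed = config$seed) {
  runs <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    cfg_k <- config
    cfg_k$seed <- as.integer(base_seed + k)
    runs[[k]] <- run_session(cfg_k)
  }
  list(table = do.call(rbind, lapply(runs, `[[`, "table")), runs = runs)
}

#' Paired Wilcoxon signed-rank test
#'
#' Exact-distribution p-value for small samples — including the tied case,
#' by full enumeration of sign assignments — and the normal approximation
#' (with tie correction) for larger samples. Zero differences are dropped
#' in the conventional way; all-zero differences give p = 1 with a
#' degeneracy flag, and fewer than 5 input pairs flags the p-value as
#' unreliable.
#'
#' @param a,b Equal-length paired samples.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (direction of `a` relative to `b`).
#' @return List with `statistic` (V, sum of positive-difference ranks),
#'   `p_value`, `method`, `degenerate`.
#' @export
wilcoxon_paired <- function(a, b,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b)) stop("samples must be paired", call. = FALSE)
  d <- a - b
  d <- d[!is.na(d)]
  n_input <- length(d)
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) {
    return(list(statistic = 0, p_value = 1,
                method = "all differences zero", degenerate = TRUE))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(r))
  if (!ties && m <= 25L) {
    p_le <- stats::psignrank(V, m)
    p_ge <- stats::psignrank(V - 1, m, lower.tail = FALSE)
    method <- "exact signed-rank"
  } else if (m <= 15L) {
    # exact by enumeration over 2^m sign assignments (handles ties)
    probs <- 1
    offs <- 0L
    r2 <- as.integer(round(2 * r))
    for (ri in r2) {
      shifted <- c(rep(0, ri), probs)
      probs <- c(probs, rep(0, ri)) + shifted
      probs <- probs / 2
    }
    w2 <- as.integer(round(2 * V))
    support <- seq_along(probs) - 1L
    p_le <- sum(probs[support <= w2])
    p_ge <- sum(probs[support >= w2])
    method <- "exact signed-rank (tie enumeration)"
  } else {
    mu <- m * (m + 1) / 4
    tie_tab <- table(r)
    sig2 <- m * (m + 1) * (2 * m + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu) / sqrt(sig2)
    p_le <- stats::pnorm(z)
    p_ge <- stats::pnorm(z, lower.tail = FALSE)
    method <- "normal approximation"
  }
  p <- switch(alternative,
              two.sided = min(1, 2 * min(p_le, p_ge)),
              greater = p_ge,
              less = p_le)
  list(statistic = V, p_value = p, method = method,
       degenerate = n_input < 5L)
}
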