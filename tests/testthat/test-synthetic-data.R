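test_that("type constructors enforce their invariants", {
  expect_error(grid_geometry(0, 7, 0.4), "n_rows")
  expect_error(grid_geometry(7, 7, -1), "spacing_mm")
  expect_error(coupling_state_model(c(0, 2), diag(2), 30), "\\[-1, 1\\]")
  bad_tm <- matrix(c(0.6, 0.5, 0.5, 0.5), 2, byrow = TRUE)  # row sums 1.1, 1
  expect_error(coupling_state_model(c(0, 0.5), bad_tm, 30), "sum to 1")
  expect_error(stimulus_paradigm(block_on_s = -30), "block_on_s")
  m <- default_coupling_model()
  expect_equal(rowSums(m$transition_matrix), rep(1, 5))
  expect_true(all(abs(m$states) <= 1))
})

test_that("generators are deterministic under a fixed seed", {
  g <- grid_geometry(2, 2, 0.4)
  b <- lfp_bands(c("delta", "alpha"))
  r1 <- generate_lfp_grid(g, 10, 100, bands = b, coherence_fwhm_mm = 1, seed = 5)
  r2 <- generate_lfp_grid(g, 10, 100, bands = b, coherence_fwhm_mm = 1, seed = 5)
  expect_identical(r1$data, r2$data)

  p1 <- generate_coupled_pair(duration_s = 120, fs_fast = 50,
                              bands = lfp_bands("delta"), seed = 9)
  p2 <- generate_coupled_pair(duration_s = 120, fs_fast = 50,
                              bands = lfp_bands("delta"), seed = 9)
  expect_identical(p1$slow$data, p2$slow$data)
  expect_identical(p1$fast$data, p2$fast$data)
  expect_identical(p1$path, p2$path)

  par <- stimulus_paradigm(n_blocks = 2)
  blob <- generate_activation_map(5, 5, 0.5, sigma_major_mm = 1,
                                  sigma_minor_mm = 0.5)
  s1 <- generate_block_design_series(par, blob, volume_interval_s = 3,
                                     amplitude = 2, noise_sd = 0.1, seed = 3)
  s2 <- generate_block_design_series(par, blob, volume_interval_s = 3,
                                     amplitude = 2, noise_sd = 0.1, seed = 3)
  expect_identical(s1$data, s2$data)
})

test_that("generated coherence matches the analytic spatial kernel", {
  # closed form: MSC(d) = exp(-4 ln2 (d/FWHM)^2); at d = FWHM/2 this is 0.5
  b <- lfp_bands("alpha")
  g <- grid_geometry(1, 2, 0.6)
  rec <- generate_lfp_grid(g, 125, 200, bands = b, coherence_fwhm_mm = 1.2,
                           seed = 1)
  sp <- msc(rec$data[1, ], rec$data[2, ], 200)
  expect_gte(sp$n_averages, 60)
  expect_equal(band_average_msc(sp, b$alpha),
               exp(-4 * log(2) * (0.6 / 1.2)^2), tolerance = 0.1 / 0.5)

  # zero-width kernel: independent channels, coherence at the bias floor
  rec0 <- generate_lfp_grid(g, 125, 200, bands = b, coherence_fwhm_mm = 0,
                            seed = 2)
  sp0 <- msc(rec0$data[1, ], rec0$data[2, ], 200)
  expect_lt(band_average_msc(sp0, b$alpha), 3 / sp0$n_averages)

  # distance ~0 relative to a wide kernel: near-identical latent source
  g_close <- grid_geometry(1, 2, 0.05)
  rec1 <- generate_lfp_grid(g_close, 60, 200, bands = b,
                            coherence_fwhm_mm = 5, seed = 3)
  sp1 <- msc(rec1$data[1, ], rec1$data[2, ], 200)
  expect_gt(band_average_msc(sp1, b$alpha), 0.97)
})

test_that("coupled-pair connectivity tracks the hidden coupling path", {
  # slow switching (dwell = 2x window) at full fidelity
  m <- default_coupling_model(dwell_s = 120)
  pair <- generate_coupled_pair(m, duration_s = 900, fs_fast = 100,
                                bands = lfp_bands("delta"), seed = 3)
  sf <- bandpass_slow(pair$slow)
  wc <- sliding_correlation(sf$data[, 1], sf$data[, 2], 3)
  path_w <- pair$path$coupling[seq_along(wc$values)]
  expect_gt(cor(wc$values, path_w, use = "complete.obs"), 0.7)
  expect_true(all(abs(pair$path$coupling) <= 1))

  # identity transition matrix: constant path, so windowed-connectivity
  # spread is estimator noise only — well below the state-driven spread of
  # the switching model above
  m_const <- coupling_state_model(0.8, matrix(1, 1, 1), 30)
  pc <- generate_coupled_pair(m_const, duration_s = 900, fs_fast = 100,
                              bands = lfp_bands("delta"), seed = 3)
  expect_equal(length(unique(pc$path$state)), 1L)
  sfc <- bandpass_slow(pc$slow)
  wcc <- sliding_correlation(sfc$data[, 1], sfc$data[, 2], 3)
  expect_lt(stats::sd(wcc$values, na.rm = TRUE),
            0.6 * stats::sd(wc$values, na.rm = TRUE))
})

test_that("coupled-pair generator rejects invalid inputs", {
  expect_error(generate_coupled_pair(low_band_fidelity = 1.2, seed = 1),
               "fidelities")
  expect_error(generate_coupled_pair(volume_interval_s = 0.0103,
                                     fs_fast = 97, seed = 1),
               "integer multiple")
})

test_that("activation maps carry exact ground truth", {
  map <- generate_activation_map(41, 41, 0.1, sigma_major_mm = 1,
                                 sigma_minor_mm = 0.5)
  expect_equal(max(map$values), 1)  # unit peak, noiseless
  peak <- which(map$values == max(map$values), arr.ind = TRUE)
  expect_equal(as.numeric((peak - 1) * 0.1), rev(map$meta$center_mm))
  expect_equal(map$meta$fwhm_major_mm, 2 * sqrt(2 * log(2)) * 1)
  expect_equal(map$meta$fwhm_major_mm, 2.3548, tolerance = 1e-4)

  # circular blob is rotation invariant
  m0 <- generate_activation_map(21, 21, 0.1, sigma_major_mm = 0.4,
                                sigma_minor_mm = 0.4, orientation_rad = 0)
  m1 <- generate_activation_map(21, 21, 0.1, sigma_major_mm = 0.4,
                                sigma_minor_mm = 0.4, orientation_rad = 0.7)
  expect_equal(m0$values, m1$values, tolerance = 1e-12)
  expect_error(generate_activation_map(5, 5, 0.1, sigma_major_mm = 0,
                                       sigma_minor_mm = 1), "sigma_major_mm")
})

test_that("block-design series follow the paradigm arithmetic", {
  par <- stimulus_paradigm(30, 30, 7)
  blob <- spatial_map(matrix(c(1, 0, 0, 0), 2, 2), 0.5)
  vs <- generate_block_design_series(par, blob, volume_interval_s = 3,
                                     baseline = 100, amplitude = 5,
                                     noise_sd = 0, seed = 1)
  expect_gte(nrow(vs$data) * 3, 420)  # 7 blocks of 30/30 plus baseline
  # noiseless: % change during on-blocks is exactly amplitude/baseline
  on <- vs$data[11:20, 1]   # first on-block volumes (after the 10 baseline)
  off <- vs$data[1:10, 1]
  expect_equal(100 * (mean(on) - mean(off)) / mean(off), 100 * 5 / 100)
  expect_equal(unique(vs$data[, 2]), 100)  # unresponsive site stays at baseline
})
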