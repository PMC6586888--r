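test_that("msc is exact for identical series and symmetric in its arguments", {
  set.seed(1)
  x <- rnorm(4000)
  y <- rnorm(4000)
  expect_equal(msc(x, x, 100)$msc, rep(1, 101))
  a <- msc(x, y, 100)
  b <- msc(y, x, 100)
  expect_identical(a$msc, b$msc)
  # invariance to channel-wise scaling
  s <- msc(3 * x, -0.5 * y, 100)
  expect_equal(s$msc, a$msc, tolerance = 1e-12)
  expect_true(all(a$msc >= 0 & a$msc <= 1))
})

test_that("msc matches the common-signal closed form and the 1/M bias", {
  # x = s+n1, y = s+n2, equal variances: MSC = (Ps/(Ps+Pn))^2 = 0.25
  set.seed(10)
  n <- 20000
  s <- rnorm(n)
  x <- s + rnorm(n)
  y <- s + rnorm(n)
  sp <- msc(x, y, 200)
  expect_gte(sp$n_averages, 60)
  expect_equal(mean(sp$msc), 0.25, tolerance = 0.07 / 0.25)

  # independent white noise: mean MSC ~ 1/M estimator bias
  set.seed(11)
  bias <- replicate(5, {
    sp0 <- msc(rnorm(n), rnorm(n), 200)
    mean(sp0$msc) * sp0$n_averages
  })
  expect_equal(mean(bias), 1, tolerance = 0.35)

  # zero-variance input is flagged missing, not zero
  spz <- msc(rep(1, 1000), rnorm(1000), 100)
  expect_true(spz$missing)
  expect_true(all(is.na(spz$msc)))
})

test_that("band averaging reduces spectra correctly", {
  spec <- structure(list(freqs = c(1, 2, 3, 4, 5),
                         msc = c(0.9, 0.2, 0.4, 0.6, 0.1),
                         n_averages = 10L, missing = FALSE),
                    class = "coherence_spectrum")
  # band covering exactly bins at 2 and 3 Hz -> mean(0.2, 0.4) = 0.3
  expect_equal(band_average_msc(spec, frequency_band("x", 2, 3)), 0.3)
  # full-spectrum band = mean of all bins
  expect_equal(band_average_msc(spec, frequency_band("all", 0.5, 5)),
               mean(spec$msc))
  # constant spectrum -> that constant
  spec$msc <- rep(0.7, 5)
  expect_equal(band_average_msc(spec, frequency_band("x", 2, 3)), 0.7)
  expect_error(band_average_msc(spec, frequency_band("none", 6, 7)),
               "overlaps no")
})

test_that("seed coherence maps have unit self-value and flag dead channels", {
  b <- lfp_bands("alpha")$alpha
  # all channels identical -> map of ones
  set.seed(2)
  x <- rnorm(3000)
  rec <- multichannel_recording(rbind(x, x, x, x), 50, grid_geometry(2, 2, 0.4))
  m <- seed_coherence_map(rec, 1, b)
  expect_equal(as.numeric(m$values), rep(1, 4), tolerance = 1e-9)
  # dead channel -> NA at that site, seed site exactly 1
  rec$data[3, ] <- 0
  m2 <- seed_coherence_map(rec, 2, b)
  expect_identical(m2$values[1, 2], 1)      # seed index 2 -> row 1, col 2
  expect_true(is.na(m2$values[2, 1]))       # channel 3 -> row 2, col 1
  expect_error(seed_coherence_map(rec, 9, b), "outside")
})

test_that("seed maps of kernel-generated grids decay with distance", {
  b <- lfp_bands("alpha")
  g <- grid_geometry(1, 5, 0.4)
  rec <- generate_lfp_grid(g, 90, 100, bands = b, coherence_fwhm_mm = 1.0,
                           seed = 8)
  m <- seed_coherence_map(rec, 1, b$alpha)
  vals <- as.numeric(m$values)
  # monotone decay in expectation along the row from the seed
  expect_true(all(diff(vals) < 0.1))
  expect_gt(vals[1] - vals[5], 0.5)
})

test_that("stimulus power-change maps recover variance modulation", {
  b <- lfp_bands("alpha")$alpha
  par <- stimulus_paradigm(30, 30, 3)
  resp <- spatial_map(matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE), 0.4)
  rec <- generate_block_design_series(par, resp, fs = 100, carrier_band = b,
                                      amplitude = 1.5, seed = 21)
  m_raw <- stimulus_power_change_map(rec, par, b, normalize = FALSE)
  # responsive channel: power rises by ~amplitude -> +150%
  expect_equal(m_raw$values[1, 1], 150, tolerance = 0.25 * 150)
  expect_lt(abs(m_raw$values[2, 2]), 40)
  # normalized map peaks at 1 at the responsive channel
  m <- stimulus_power_change_map(rec, par, b)
  expect_equal(max(m$values, na.rm = TRUE), 1)
  expect_equal(which.max(t(m$values)), 1L)
  # no-response recording: map hovers near zero before normalization
  resp0 <- spatial_map(matrix(0, 2, 2), 0.4)
  rec0 <- generate_block_design_series(par, resp0, fs = 100, carrier_band = b,
                                       amplitude = 0, seed = 22)
  m0 <- stimulus_power_change_map(rec0, par, b, normalize = FALSE)
  expect_lt(max(abs(m0$values)), 40)
})
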