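test_that("bilinear upsampling is exact at nodes and for linear fields", {
  m <- spatial_map(matrix(runif(25, 0, 1), 5, 5), 1)
  up <- upsample_map(m, 0.5)
  # original nodes preserved exactly
  expect_equal(up$values[seq(1, 9, 2), seq(1, 9, 2)], m$values)
  # constant map stays constant
  cm <- upsample_map(spatial_map(matrix(2, 4, 4), 1), 0.25)
  expect_equal(unique(as.numeric(cm$values)), 2)
  # linear ramp reproduced exactly
  ramp <- spatial_map(outer(0:4, 0:4, function(i, j) 2 * i + 3 * j), 1)
  upr <- upsample_map(ramp, 0.5)
  truth <- outer(seq(0, 4, 0.5), seq(0, 4, 0.5), function(y, x) 2 * y + 3 * x)
  expect_equal(upr$values, truth, tolerance = 1e-12)
  expect_error(upsample_map(m, 2), "finer")
  expect_error(upsample_map(m, -1), "target_resolution_mm")
})

test_that("centre of mass respects threshold and symmetry", {
  v <- matrix(0, 5, 5); v[2, 4] <- 1
  m <- spatial_map(v, 0.5)
  expect_equal(as.numeric(center_of_mass(m)), c(3, 1) * 0.5)  # (x, y)
  blob <- generate_activation_map(31, 31, 0.1, sigma_major_mm = 0.5,
                                  sigma_minor_mm = 0.5)
  com <- center_of_mass(blob)
  expect_equal(as.numeric(com), blob$meta$center_mm, tolerance = 0.05)
  expect_false(attr(com, "multi_focus"))
  # two equal blobs: centroid at the midpoint, flagged multi-focus
  v2 <- matrix(0, 5, 9); v2[3, 2] <- 1; v2[3, 8] <- 1
  com2 <- center_of_mass(spatial_map(v2, 1))
  expect_equal(as.numeric(com2), c(4, 2))
  expect_true(attr(com2, "multi_focus"))
  expect_error(center_of_mass(spatial_map(v / 10, 0.5), threshold = 0.7), NA)
  # threshold on a normalized map always leaves the peak, so use all-NA-free
  expect_error(center_of_mass(spatial_map(matrix(c(1, rep(NA, 8)), 3, 3), 1),
                              threshold = 2), "threshold")
})

test_that("axis profiles truncate at the value floor as the closed form says", {
  blob <- generate_activation_map(81, 81, 0.05, sigma_major_mm = 1,
                                  sigma_minor_mm = 1)
  com <- center_of_mass(blob)
  prof <- extract_axis_profile(blob, com, 0, value_floor = 0.2,
                               step_mm = 0.01)
  # exp(-x^2/2) = 0.2 at x = sqrt(2 ln 5) ~ 1.794
  half_len <- max(prof$pos_mm)
  expect_equal(half_len, sqrt(2 * log(5)), tolerance = 0.02)
  expect_true(all(prof$value >= 0.2 - 1e-9))
  # flat map: full line retained
  flat <- spatial_map(matrix(1, 11, 11), 0.5)
  pf <- extract_axis_profile(flat, c(2.5, 2.5), 0, step_mm = 0.5)
  expect_gte(diff(range(pf$pos_mm)), 5 - 1e-9)
  expect_error(extract_axis_profile(blob, c(100, 100), 0), "outside")
})

test_that("1-D Gaussian fits recover the closed-form FWHM", {
  x <- seq(-3, 3, by = 0.05)
  prof <- data.frame(pos_mm = x, value = exp(-x^2 / 2))
  fit <- fit_gaussian_1d(prof)
  expect_true(fit$converged)
  expect_equal(fit$fwhm, 2 * sqrt(2 * log(2)), tolerance = 1e-6)
  expect_equal(fit$fwhm, 2.3548, tolerance = 1e-4)
  # sigma = 0.5 -> fwhm 1.1774
  prof2 <- data.frame(pos_mm = x, value = exp(-x^2 / (2 * 0.25)))
  expect_equal(fit_gaussian_1d(prof2)$fwhm, 1.1774, tolerance = 1e-4)
  # amplitude scaling leaves the width unchanged
  prof10 <- data.frame(pos_mm = x, value = 10 * exp(-x^2 / 2))
  expect_equal(fit_gaussian_1d(prof10)$fwhm, fit$fwhm, tolerance = 1e-6)
  expect_error(fit_gaussian_1d(prof[1:3, ]), "at least 5")
})

test_that("elliptical PSF fits recover axis ratio, area identity and scale invariance", {
  blob <- generate_activation_map(81, 81, 0.05, sigma_major_mm = 1,
                                  sigma_minor_mm = 0.5)
  fit <- fit_elliptical_psf(blob, major_axis_rad = 0, profile_step_mm = 0.02)
  expect_equal(fit$fwhm_major_mm / fit$fwhm_minor_mm, 2, tolerance = 0.01)
  expect_identical(fit$area_mm2,
                   pi * (fit$fwhm_major_mm / 2) * (fit$fwhm_minor_mm / 2))
  # scale invariance: x50 map -> identical fit
  blob50 <- spatial_map(blob$values * 50, blob$resolution_mm)
  fit50 <- fit_elliptical_psf(blob50, 0, profile_step_mm = 0.02)
  expect_equal(fit50$fwhm_major_mm, fit$fwhm_major_mm, tolerance = 1e-6)
  # circular blob: area = pi (fwhm/2)^2
  circ <- generate_activation_map(61, 61, 0.05, sigma_major_mm = 0.5,
                                  sigma_minor_mm = 0.5)
  fc <- fit_elliptical_psf(circ, 0, profile_step_mm = 0.02)
  expect_equal(fc$area_mm2, pi * (fc$fwhm_major_mm / 2)^2, tolerance = 1e-6)
})

test_that("fitted FWHM grows monotonically with generating sigma", {
  sigmas <- c(0.3, 0.5, 0.8, 1.2)
  fwhms <- vapply(sigmas, function(s) {
    blob <- generate_activation_map(81, 81, 0.05, sigma_major_mm = s,
                                    sigma_minor_mm = s)
    fit_elliptical_psf(blob, 0, profile_step_mm = 0.05)$fwhm_major_mm
  }, numeric(1))
  expect_true(all(diff(fwhms) > 0))
})

test_that("noisy blobs recover FWHM within 5% across seeds", {
  k <- 2 * sqrt(2 * log(2))
  errs <- vapply(1:20, function(s) {
    blob <- generate_activation_map(81, 81, 0.05, sigma_major_mm = 0.8,
                                    sigma_minor_mm = 0.6, noise_sd = 0.05,
                                    seed = 400 + s)
    fit <- fit_elliptical_psf(blob, 0, profile_step_mm = 0.05)
    abs(fit$fwhm_major_mm - k * 0.8) / (k * 0.8)
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("2-D cross-check fit and axis helper agree with the 1-D pipeline", {
  blob <- generate_activation_map(61, 61, 0.1, sigma_major_mm = 1,
                                  sigma_minor_mm = 0.5,
                                  orientation_rad = 0)
  f2 <- fit_gaussian_2d(blob)
  expect_true(f2$converged)
  expect_equal(f2$fwhm_major_mm, blob$meta$fwhm_major_mm, tolerance = 0.01)
  expect_equal(f2$fwhm_minor_mm, blob$meta$fwhm_minor_mm, tolerance = 0.01)
  # major axis through collinear activation centres
  ang <- major_axis_from_centers(rbind(c(0, 0), c(1, 1), c(2, 2)))
  expect_equal(ang, pi / 4, tolerance = 1e-9)
  expect_error(major_axis_from_centers(rbind(c(0, 0))), "at least 2")
})
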