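test_that("window bookkeeping matches floor((T - W)/step) + 1 exactly", {
  # the canonical case: 300 volumes at 3 s, 60 s window, 3 s step -> 281
  a <- sin(seq_len(300)); b <- cos(seq_len(300))
  wc <- sliding_correlation(a, b, 3, window_s = 60, step_s = 3)
  expect_length(wc$values, 281)
  # property over a parameter grid
  for (n in c(50, 127, 300)) {
    for (w in c(5, 20, 50)) {
      for (st in c(1, 3, 7)) {
        x <- rnorm(n)
        wcn <- sliding_correlation(x, rev(x), 1, window_s = w, step_s = st)
        expect_length(wcn$values, floor((n - w) / st) + 1)
      }
    }
  }
})

test_that("sliding correlation hits the exact endpoints and flags degeneracy", {
  set.seed(3)
  a <- rnorm(300)
  wc1 <- sliding_correlation(a, a, 3, 60, 3)
  expect_true(all(abs(wc1$values - 1) < 1e-12))
  wcm <- sliding_correlation(a, -a, 3, 60, 3)
  expect_true(all(abs(wcm$values + 1) < 1e-12))
  # zero-variance window propagates NA rather than being dropped
  b <- rnorm(300); b[1:40] <- 5
  wcz <- sliding_correlation(b, rep(1, 300) * c(rep(1, 40), rnorm(260)), 3, 60, 3)
  expect_true(anyNA(wcz$values))
  expect_length(wcz$values, 281)
  expect_error(sliding_correlation(a, a[-1], 3), "equal length")
})

test_that("windowed correlation converges to the population r as windows grow", {
  set.seed(4)
  n <- 6000
  s <- rnorm(n)
  a <- sqrt(0.5) * s + sqrt(0.5) * rnorm(n)
  b <- sqrt(0.5) * s + sqrt(0.5) * rnorm(n)   # population r = 0.5
  for (w in c(100, 400)) {
    wc <- sliding_correlation(a, b, 1, window_s = w, step_s = 50)
    expect_equal(mean(wc$values), 0.5, tolerance = 0.1)
  }
  # longer windows shrink the spread around the population value
  sd_short <- sd(sliding_correlation(a, b, 1, 100, 50)$values)
  sd_long <- sd(sliding_correlation(a, b, 1, 400, 50)$values)
  expect_lt(sd_long, sd_short)
})

test_that("sliding band coherence mirrors msc behaviour per window", {
  alpha <- lfp_bands("alpha")$alpha
  set.seed(5)
  x <- rnorm(5000)
  wc <- sliding_band_coherence(x, x, 100, alpha, window_s = 10, step_s = 5)
  expect_true(all(wc$values > 1 - 1e-9))
  # independent noise fluctuates around the 1/M bias level
  y <- rnorm(5000)
  wcb <- sliding_band_coherence(x, y, 100, alpha, window_s = 10, step_s = 5)
  m_avg <- msc(x[1:1000], y[1:1000], 100)$n_averages
  expect_lt(mean(wcb$values), 3 / m_avg)
  # coupling switched off mid-run: window means drop after the switch
  s <- band_limited_noise_test(5000, 100, 9, 14)
  x2 <- s + 0.3 * rnorm(5000)
  y2 <- c(s[1:2500] + 0.3 * rnorm(2500), rnorm(2500))
  wcs <- sliding_band_coherence(x2, y2, 100, alpha, window_s = 10, step_s = 5)
  n_w <- length(wcs$values)
  expect_gt(mean(wcs$values[1:floor(n_w / 2 - 1)]),
            mean(wcs$values[ceiling(n_w / 2 + 2):n_w]) + 0.3)
})

test_that("Fisher z matches arctanh and inverts cleanly", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4 / 0.5493)
  expect_equal(fisher_z(0.5), atanh(0.5))
  r <- seq(-0.99, 0.99, by = 0.01)
  expect_equal(inverse_fisher_z(fisher_z(r)), r, tolerance = 1e-12)
  # clipping keeps +/-1 finite
  expect_true(is.finite(fisher_z(1)) && is.finite(fisher_z(-1)))
})

test_that("state binning follows the half-open edge convention", {
  # domain endpoints map to states 1 and 50
  s <- bin_states(c(-1, 1), 50, domain = c(-1, 1))
  expect_identical(s$states, c(1L, 50L))
  # edges at -1 + 0.04k: 0.02 falls in [0, 0.04) -> state 26
  expect_identical(bin_states(0.02, 50, c(-1, 1))$states, 26L)
  # constant series -> constant states; clamping beyond the domain
  expect_identical(unique(bin_states(rep(0.5, 10), 50, c(-1, 1))$states), 38L)
  expect_identical(bin_states(c(-2, 2), 50, c(-1, 1))$states, c(1L, 50L))
  # missing values stay missing and are counted
  sm <- bin_states(c(0.1, NA, 0.2), 50, c(-1, 1))
  expect_identical(sm$n_missing, 1L)
  expect_error(bin_states(1:3, 50, c(1, -1)), "lo < hi")
})

test_that("state binning is monotone and measure-aware", {
  set.seed(6)
  v <- sort(runif(200, -1, 1))
  st <- bin_states(v, 50, c(-1, 1))$states
  expect_true(all(diff(st) >= 0))
  # coherence measures default to the [0, 1] domain
  wc <- windowed_connectivity(seq(0, 1, length.out = 20), 60, 3,
                              measure = "band_msc")
  sc <- bin_states(wc)
  expect_identical(sc$domain, c(0, 1))
  expect_identical(sc$states[c(1, 20)], c(1L, 50L))
  # r measures default to [-1, 1]; clipped-z variant stays in range
  wr <- windowed_connectivity(c(-0.9, 0, 0.9), 60, 3, measure = "pearson_r")
  expect_identical(bin_states(wr)$domain, c(-1, 1))
  sz <- bin_states(wr, on = "z_clipped")
  expect_true(all(sz$states >= 1 & sz$states <= 50))
})
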