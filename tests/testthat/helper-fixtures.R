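# Shared fixtures: tiny deterministic signals and models built in code.

tone_recording <- function(freq_hz, fs = 500, duration_s = 20, amplitude = 1,
                           n_channels = 1) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  dat <- matrix(rep(amplitude * sin(2 * pi * freq_hz * t), n_channels),
                nrow = n_channels, byrow = TRUE)
  multichannel_recording(dat, fs, grid_geometry(1, n_channels, 1))
}

noise_recording <- function(fs = 500, duration_s = 20, n_channels = 1,
                            seed = 42) {
  set.seed(seed)
  dat <- matrix(rnorm(n_channels * round(fs * duration_s)), nrow = n_channels)
  multichannel_recording(dat, fs, grid_geometry(1, n_channels, 1))
}

state_seq <- function(states, n_states = 50, domain = c(-1, 1)) {
  structure(list(states = as.integer(states), n_states = as.integer(n_states),
                 domain = domain, n_missing = sum(is.na(states))),
            class = "state_sequence")
}

# Brute-force two-sample K-S oracle: double loop over the union of
# observed jump values, plain proportions.
ks_brute_force <- function(jumps_a, jumps_b) {
  u <- sort(unique(c(jumps_a, jumps_b)))
  d <- 0
  for (v in u) {
    fa <- sum(jumps_a <= v) / length(jumps_a)
    fb <- sum(jumps_b <= v) / length(jumps_b)
    d <- max(d, abs(fa - fb))
  }
  d
}

band_limited_noise_test <- function(n, fs, f_low, f_high, seed = 99) {
  set.seed(seed)
  dynfc:::band_limited_noise(n, fs, f_low, f_high)
}
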