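test_that("jump distributions enumerate signed single-step transitions", {
  # constant sequence: unit step at 0
  jd <- jump_distribution(state_seq(rep(7, 10)))
  expect_true(all(jd$jumps == 0))
  expect_equal(jd$ecdf(0), 1)
  expect_equal(jd$ecdf(-1), 0)
  # (1, 2, 1): jumps {+1, -1}
  jd2 <- jump_distribution(state_seq(c(1, 2, 1)))
  expect_setequal(jd2$jumps, c(1L, -1L))
  expect_equal(jd2$ecdf(-1), 0.5)
  expect_equal(jd2$ecdf(1), 1)
  # strictly increasing: n-1 jumps of +1
  jd3 <- jump_distribution(state_seq(1:12))
  expect_identical(jd3$jumps, rep(1L, 11))
  # missing states break transitions (no jump across the gap)
  jd4 <- jump_distribution(state_seq(c(1, 2, NA, 5, 6)))
  expect_identical(sort(jd4$jumps), c(1L, 1L))
  expect_identical(jd4$n, 2L)
  expect_error(jump_distribution(state_seq(c(NA, NA, NA))), "missing")
  expect_error(jump_distribution(state_seq(3L)), "at least 2")
  # absolute variant folds the sign
  jd5 <- jump_distribution(state_seq(c(1, 3, 1)), absolute = TRUE)
  expect_identical(jd5$jumps, c(2L, 2L))
})

test_that("worked K-S examples are exact", {
  # jumps {0,0,1} vs {0,1,1}: ECDFs 2/3 vs 1/3 at 0 -> D = 1/3
  a <- jump_distribution(state_seq(c(1, 1, 1, 2)))   # jumps 0,0,1
  b <- jump_distribution(state_seq(c(1, 1, 2, 3)))   # jumps 0,1,1
  expect_equal(ks_two_sample(a, b)$statistic, 1 / 3)
  # identical jump multisets -> 0
  expect_equal(ks_two_sample(a, a)$statistic, 0)
  # disjoint supports -> 1
  lo <- jump_distribution(state_seq(c(5, 3, 1)))     # jumps all -2
  hi <- jump_distribution(state_seq(c(1, 3, 5)))     # jumps all +2
  expect_equal(ks_two_sample(lo, hi)$statistic, 1)
})

test_that("K-S equals the brute-force oracle and stats::ks.test, and is symmetric", {
  set.seed(123)
  for (i in 1:50) {
    sa <- state_seq(sample.int(50, sample(3:50, 1), replace = TRUE))
    sb <- state_seq(sample.int(50, sample(3:50, 1), replace = TRUE))
    ja <- jump_distribution(sa)
    jb <- jump_distribution(sb)
    d_pkg <- ks_two_sample(ja, jb)$statistic
    expect_identical(d_pkg, ks_brute_force(ja$jumps, jb$jumps))
    expect_identical(d_pkg, ks_two_sample(jb, ja)$statistic)
    # independent implementation of the same sup-distance
    d_ref <- suppressWarnings(
      stats::ks.test(ja$jumps, jb$jumps)$statistic)
    expect_equal(d_pkg, unname(d_ref), tolerance = 1e-12)
    expect_gte(d_pkg, 0)
    expect_lte(d_pkg, 1)
  }
})

test_that("band profiles are bandwise-independent and zero on self-comparison", {
  set.seed(9)
  slow <- state_seq(sample.int(50, 100, replace = TRUE))
  fast <- list(delta = slow,
               gamma = state_seq(sample.int(50, 100, replace = TRUE)))
  prof <- ks_band_profile(slow, fast)
  expect_equal(prof$ks_statistic[prof$band == "delta"], 0)
  # permuting the band order permutes rows identically
  prof_rev <- ks_band_profile(slow, rev(fast))
  expect_equal(prof_rev$ks_statistic[match(prof$band, prof_rev$band)],
               prof$ks_statistic)
})

test_that("mean K-S against the slow modality rises as fidelity falls", {
  # fidelity sweep {1, 0.5, 0} on the end-to-end generator; sign test over
  # seeds on the monotone ordering
  bands <- lfp_bands("delta")
  ks_at <- function(fid, seed) {
    pair <- generate_coupled_pair(duration_s = 450, fs_fast = 60,
                                  low_band_fidelity = fid,
                                  high_band_fidelity = fid,
                                  bands = bands, seed = seed)
    sf <- bandpass_slow(pair$slow)
    wc_s <- sliding_correlation(sf$data[, 1], sf$data[, 2], 3)
    wc_f <- sliding_band_coherence(pair$fast$data[1, ], pair$fast$data[2, ],
                                   60, bands$delta)
    ks_two_sample(jump_distribution(bin_states(wc_s)),
                  jump_distribution(bin_states(wc_f)))$statistic
  }
  seeds <- 1:10
  k1 <- vapply(seeds, function(s) ks_at(1, 700 + s), numeric(1))
  k0 <- vapply(seeds, function(s) ks_at(0, 700 + s), numeric(1))
  k5 <- vapply(seeds, function(s) ks_at(0.5, 700 + s), numeric(1))
  expect_lt(mean(k1), mean(k5))
  expect_lt(mean(k5), mean(k0))
  # sign test: full-fidelity beats zero-fidelity in >= 9/10 seeds
  expect_gte(sum(k1 < k0), 9)
})

test_that("transition-matrix distance diagnostic separates unlike dynamics", {
  set.seed(31)
  a <- state_seq(sample.int(10, 200, replace = TRUE), n_states = 10)
  expect_equal(transition_matrix_distance(a, a), 0)
  b <- state_seq(rep(c(1L, 10L), 100), n_states = 10)
  expect_gt(transition_matrix_distance(a, b), 0.5)
})
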