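#!/usr/bin/env Rscript
# Step 4 — Fourier composition of connectivity fluctuations.
#
# Decomposes every windowed-connectivity series (slow-modality correlation
# and per-band coherence) into its fluctuation spectrum and summarizes the
# percentage of power in five slow bands (<0.0025 to >0.02 Hz), then
# compares the two LFP bands per fluctuation band with a paired Wilcoxon
# signed-rank test across runs.
#
# Expected shape under the synthetic coupling model: the full-fidelity low
# band inherits the Markov path's switching spectrum, so its variation
# concentrates at the path's characteristic frequencies (below ~1/dwell
# Hz); the zero-fidelity high band carries no coupling dynamics, so its
# residual variation is coherence-estimator noise spread roughly evenly
# across fluctuation frequencies.  The normalized percentages therefore
# separate the two bands in every fluctuation band where the path has
# power.

library(dynfc)

seed <- 43
n_runs <- 6
bands <- lfp_bands(c("delta", "gamma_high"))
dir.create("results", showWarnings = FALSE)

spectra <- list(slow = list(), delta = list(), gamma_high = list())
for (r in 1:n_runs) {
  cfg <- session_config(seed = seed * 100 + r, bands = bands,
                        stages = "dynamics")
  res <- suppressMessages(run_session(cfg))
  spectra$slow[[r]] <- variation_spectrum(res$dynamics$wc_slow)
  for (bn in names(bands)) {
    spectra[[bn]][[r]] <- variation_spectrum(res$dynamics$wc_bands[[bn]]$coherence)
  }
  message(sprintf("run %d/%d done", r, n_runs))
}

frac_rows <- do.call(rbind, lapply(names(spectra), function(cond) {
  do.call(rbind, lapply(seq_len(n_runs), function(r) {
    cb <- spectra[[cond]][[r]]$cumulative_bands
    data.frame(run = r, condition = cond, band = names(cb),
               percent = as.numeric(cb))
  }))
}))
write.csv(frac_rows, "results/variation_fractions.csv", row.names = FALSE)

cmp <- compare_band_variation(list(delta = spectra$delta,
                                   gamma_high = spectra$gamma_high))
write.csv(cmp, "results/variation_band_tests.csv", row.names = FALSE)

message("\nmean percentage of connectivity variation per fluctuation band:")
agg <- aggregate(percent ~ band + condition, frac_rows, mean)
print(agg, row.names = FALSE, digits = 3)
message("\ndelta vs gamma-high paired Wilcoxon per fluctuation band:")
print(cmp[, c("band", "mean_a", "mean_b", "p_value")], row.names = FALSE,
      digits = 3)
message("\nthe low band's variation rides on the slow Markov switching; ",
        "the dynamics-free high band's residual variation is flat ",
        "estimator noise, so its normalized spectrum is comparatively ",
        "broadband.")
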