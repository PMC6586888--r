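#!/usr/bin/env Rscript
# Step 3 — sliding-window coherence between the two regions, comparing a
# low band (delta) with a high band (gamma high) at 30 s and 60 s windows.
#
# The low band's windowed coherence follows the hidden coupling path and
# therefore fluctuates visibly; the high band (generated here with zero
# path fidelity) stays near its constant level.  Shorter windows trade
# estimator variance for temporal resolution.

library(dynfc)

seed <- 42
dir.create("results", showWarnings = FALSE)

pair <- generate_coupled_pair(bands = lfp_bands(c("delta", "gamma_high")),
                              low_band_fidelity = 1, high_band_fidelity = 0,
                              seed = seed)

rows <- list()
for (w in c(30, 60)) {
  for (bn in c("delta", "gamma_high")) {
    wc <- sliding_band_coherence(pair$fast$data[1, ], pair$fast$data[2, ],
                                 500, lfp_bands(bn)[[bn]],
                                 window_s = w, step_s = 3)
    rows[[length(rows) + 1L]] <- data.frame(
      band = bn, window_s = w, window_start_s = wc$times, msc = wc$values)
    message(sprintf("%-11s window %2d s: %d windows, mean MSC %.3f, sd %.3f",
                    bn, w, length(wc$values), mean(wc$values),
                    sd(wc$values)))
  }
}
out <- do.call(rbind, rows)
write.csv(out, "results/sliding_window_coherence.csv", row.names = FALSE)
message("wrote results/sliding_window_coherence.csv")
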