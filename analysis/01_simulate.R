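#!/usr/bin/env Rscript
# Step 1 — generate one example synthetic session and write its raw data.
#
# Produces, under results/data/:
#   * a Markov-coupled slow (2-ROI, 3 s volumes) / fast (2-channel, 500 Hz)
#     signal pair with the true coupling path,
#   * a 7x7 electrode-grid resting recording with a 1.2 mm coherence kernel,
#   * a noiseless and a noisy elliptical activation map.

library(dynfc)

seed <- 20190620
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("simulating coupled slow/fast pair (900 s, 8 bands)...")
pair <- generate_coupled_pair(seed = seed)
write_volume_series_csv(pair$slow, file.path(out, "slow_pair.csv"))
write_recording_csv(pair$fast, file.path(out, "fast_pair.csv"))
write.csv(pair$path, file.path(out, "true_state_path.csv"), row.names = FALSE)
message(sprintf("  %d volumes, %d fast samples, %d state changes",
                nrow(pair$slow$data), ncol(pair$fast$data),
                sum(diff(pair$path$state) != 0)))

message("simulating 7x7 grid resting recording (alpha band, 120 s)...")
grid <- generate_lfp_grid(grid_geometry(7, 7, 0.4), 120, 500,
                          bands = lfp_bands("alpha"),
                          coherence_fwhm_mm = 1.2, seed = seed + 1)
write_recording_csv(grid, file.path(out, "grid_rest_alpha.csv"))

message("simulating activation maps...")
clean <- generate_activation_map(81, 81, 0.05, sigma_major_mm = 1,
                                 sigma_minor_mm = 0.5)
noisy <- generate_activation_map(81, 81, 0.05, sigma_major_mm = 1,
                                 sigma_minor_mm = 0.5, noise_sd = 0.05,
                                 seed = seed + 2)
write_map_csv(clean, file.path(out, "activation_clean.csv"))
write_map_csv(noisy, file.path(out, "activation_noisy.csv"))

message("wrote raw session data to ", out)
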