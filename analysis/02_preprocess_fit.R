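#!/usr/bin/env Rscript
# Step 2 — preprocess the raw stacks and fit the three-pool model.
#
# Re-simulates the step-1 acquisition (same seed), runs the preprocessing
# chain (per-channel polarity correction, coil-sensitivity estimation and
# combination, frequency difference mapping, spatial cubic detrend with
# the callosum excluded from the trend estimation, per-segment ROI
# averaging) and fits the joint magnitude+FDM three-pool model per
# segment.

library(fdm3pool)

seed <- 1L
ph <- generate_phantom(phantom_spec(grid = c(96L, 96L)), seed = seed)
stack <- simulate_acquisition(ph, nuisance_spec(), seed = seed + 1L)

pp <- preprocess_stack(stack)
dir.create("results", showWarnings = FALSE)
write_roi_curves_csv(pp$curves, "results/02_roi_curves.csv")

truth <- read.csv("results/01_truth_segment_means.csv")
fits <- lapply(pp$curves, fit_three_pool)
tab <- data.frame(
  segment = 1:3,
  f_m = vapply(fits, function(f) f$fractions_normalized[["f_m"]], numeric(1)),
  omega_a_hz = vapply(fits, function(f) omega_hz(f$params)[["omega_a_hz"]], numeric(1)),
  omega_m_hz = vapply(fits, function(f) omega_hz(f$params)[["omega_m_hz"]], numeric(1)),
  delta_omega_hz = vapply(fits, function(f) f$delta_omega_hz, numeric(1)),
  f_m_truth = truth$f_m,
  delta_omega_truth_hz = truth$delta_omega_hz)
write.csv(tab, "results/02_segment_fits.csv", row.names = FALSE)

message("per-segment fits (noisy acquisition, pixel SNR 100):")
print(tab, digits = 3)
message(sprintf("max |f_m - truth| = %.3f", max(abs(tab$f_m - tab$f_m_truth))))
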