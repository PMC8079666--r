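#!/usr/bin/env Rscript
# Step 3 — sensitivity of the fractions to the fixed intra-axonal decay.
#
# The fit holds R2*_a at 0 because the 31 ms maximum TE cannot constrain
# the slowly decaying intra-axonal pool. This experiment quantifies the
# cost: simulate noiseless posterior-segment curves with a non-zero true
# R2*_a, refit under the constraint, and tabulate the signed fraction
# errors.

library(fdm3pool)

bias <- r2a_constraint_bias(seq(0, 10, by = 2.5))
dir.create("results", showWarnings = FALSE)
write.csv(bias, "results/03_r2a_constraint_bias.csv", row.names = FALSE)

message("bias from fixing R2*_a = 0 (noiseless posterior-segment curves):")
print(bias[, c("r2s_a_true", "err_f_m", "err_f_a", "err_f_e")], digits = 3)
message("the intra-axonal fraction is underestimated and the extra-axonal")
message("fraction overestimated as the true rate grows; the myelin fraction")
message(sprintf("moves far less (|err| <= %.3f at R2*_a = 10/s).",
                abs(bias$err_f_m[bias$r2s_a_true == 10])))
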