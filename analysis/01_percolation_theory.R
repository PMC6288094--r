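#!/usr/bin/env Rscript
# Percolation ground truth for the pipeline.
#
# 1. Locates the Moore-neighbourhood critical occupancy by a spanning-
#    probability scan with finite-size extrapolation.
# 2. Traces the phase behaviour of the largest-patch proportion RSmax
#    across occupancy (sigmoidal crossing at p_c).
# 3. Fits the patch-size power law on critical lattices and compares the
#    mean exponent with the 2D isotropic-percolation value (about 2.055).
#
# Writes: results/percolation_scan.csv, results/rsmax_phase.csv,
#         results/critical_exponents.csv

library(fragcrit)
dir.create("results", showWarnings = FALSE)
seed <- 1L

message("== spanning-probability scan ==")
scan <- critical_occupancy(L_values = c(256, 512, 1024), seed = seed)
scan_df <- data.frame(L = c(256, 512, 1024, Inf),
                      p_c = c(unname(scan$by_L), scan$p_c))
write.csv(scan_df, "results/percolation_scan.csv", row.names = FALSE)
message(sprintf("critical occupancy (extrapolated): %.5f", scan$p_c))

message("== RSmax phase curve (L = 512) ==")
ps <- seq(0.30, 0.55, by = 0.025)
phase <- do.call(rbind, lapply(ps, function(p) {
  rs <- vapply(1:8, function(r)
    label_patches(percolation_lattice(512, p, seed = 1000 + 100 * r + round(1e3 * p)))$rs_max,
    numeric(1))
  data.frame(p = p, rs_max_mean = mean(rs), rs_max_sd = sd(rs))
}))
write.csv(phase, "results/rsmax_phase.csv", row.names = FALSE)
message(sprintf("RSmax at p = 0.30: %.3f | at p_c: %.3f | at p = 0.55: %.3f",
                phase$rs_max_mean[phase$p == 0.30],
                phase$rs_max_mean[which.min(abs(phase$p - scan$p_c))],
                phase$rs_max_mean[phase$p == 0.55]))

message("== critical exponent at L = 2048 ==")
alphas <- critical_alpha(scan$p_c, L = 2048, reps = 10, seed = 100)
write.csv(data.frame(replicate = seq_along(alphas), alpha = alphas),
          "results/critical_exponents.csv", row.names = FALSE)
message(sprintf("mean fitted exponent: %.4f (universality value 2.05495)",
                mean(alphas)))
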