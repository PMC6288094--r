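#!/usr/bin/env Rscript
# Contact-process forest dynamics: a two-state (forest / non-forest)
# birth-death lattice model with an absorbing empty state. Illustrates the
# two phases the empirical diagnostics are meant to separate: extinction
# (fragmentation collapse) below the critical colonisation rate,
# quasi-stationary persistence above it.
#
# Writes: results/contact_process_density.csv

library(fragcrit)
dir.create("results", showWarnings = FALSE)

runs <- list(subcritical = 0.8, near = 1.6, supercritical = 4)
rows <- list()
for (nm in names(runs)) {
  lambda <- runs[[nm]]
  snaps <- contact_process(128, lambda, years = 60, init_density = 0.5,
                           seed = 42)
  dens <- vapply(snaps, function(s) mean(s$mask), numeric(1))
  rows[[nm]] <- data.frame(regime = nm, lambda = lambda,
                           year = seq_along(dens), density = dens)
  message(sprintf("lambda = %.1f (%s): final density %.3f", lambda, nm,
                  dens[length(dens)]))
}
write.csv(do.call(rbind, rows), "results/contact_process_density.csv",
          row.names = FALSE)
message("mean-field quasi-stationary anchor: rho* = 1 - 1/lambda")
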