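#!/usr/bin/env Rscript
# Loss of mimicry polymorphism under NFDS, positive selection and drift.
#
# Runs the two built-in simulation designs of the NFDS model:
#   (a) the 8-scenario selection grid crossed with z and p0 (supplementary-
#       style sweep) at a single moderate Ne, and
#   (b) the selection-by-drift fixation design (a = b in 1..2 crossed with
#       Ne in 1e2..1e5 at z = 0.25, p0 = 0.25, 400 generations, 10 runs).
# Writes one TSV per design under results/.

suppressMessages(library(mimicrysim))
dir.create("results", showWarnings = FALSE)
seed <- 20260930L

message("Deterministic equilibria of the pure-NFDS map:")
for (z in c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  eq <- nfds_equilibrium(nfds_params(z = z, a = 1, b = 1, p0 = 0.25))
  message(sprintf("  z = %.2f -> p* = %.6f (analytic 1 - sqrt(1/2) = %.6f)",
                  z, eq$p_star, 1 - sqrt(0.5)))
}

message("Scenario grid (8 selection regimes x 5 z x 5 p0, Ne = 1000) ...")
grid <- nfds_preset_grid("scenario-grid", Ne = 1000)
sweep <- parameter_sweep(grid, n_generations = 400, n_runs = 10, seed = seed)
write.table(sweep, "results/nfds_scenario_grid.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
agg <- aggregate(fixation_frequency ~ scenario, sweep, mean)
message("  mean fixation frequency by scenario (over z and p0):")
for (i in seq_len(nrow(agg)))
  message(sprintf("    scenario %d (a=%g, b=%g): %.3f", agg$scenario[i],
                  grid$a[match(agg$scenario[i], grid$scenario)],
                  grid$b[match(agg$scenario[i], grid$scenario)],
                  agg$fixation_frequency[i]))
message("  pure NFDS (scenario 1) rows with any fixation: ",
        sum(sweep$fixed[sweep$scenario == 1] > 0))

message("Fixation-by-Ne design (z = 0.25, p0 = 0.25, 400 generations) ...")
g2 <- nfds_preset_grid("fixation-by-Ne")
s2 <- parameter_sweep(g2, n_generations = 400, n_runs = 10, seed = seed + 1L)
write.table(s2, "results/nfds_fixation_by_Ne.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
for (ab in unique(s2$a))
  message(sprintf("  a=b=%-5g fixation freq by Ne (1e2,1e3,1e4,1e5): %s", ab,
                  paste(sprintf("%.1f", s2$fixation_frequency[s2$a == ab]),
                        collapse = " ")))
message("Interpretation: at moderate frequency dependence (z = 0.25) pure ",
        "NFDS never fixes the mimetic allele at any population size; with a ",
        "positive mimicry benefit it fixes only when drift is strong (small ",
        "Ne) - selection and drift act together.")
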