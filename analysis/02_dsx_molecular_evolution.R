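#!/usr/bin/env Rscript
# Molecular evolution of the supergene coding sequence under purifying
# selection and founder hitchhiking.
#
# Simulates the two-phase scenario (constant-size non-mimetic population;
# mimetic population founded by one haplotype drawn from it) five times,
# classifies variation against the known GMRCA into the MK table, compares
# mimetic vs non-mimetic tables with the 4x2 exact test, and summarizes
# Ka/Ks per haplotype. Writes results/mk_tables.tsv and
# results/omega_summary.tsv plus a FASTA of the first replicate.

suppressMessages({
  library(mimicrysim)
  library(Biostrings)
})
dir.create("results", showWarnings = FALSE)
seed <- 20260930L

gmrca <- generate_gmrca(300, seed = seed)
scen <- codon_scenario("mimetic-two-phase", N = 500)
reps <- 5

rows <- list()
om_rows <- list()
for (i in seq_len(reps)) {
  set.seed(seed + i)
  run <- run_scenario(scen, gmrca)
  for (grp in names(run$samples)) {
    mk <- classify_sites(run$samples[[grp]], gmrca)
    om <- omega_summary(run$samples[[grp]], gmrca)
    rows[[length(rows) + 1]] <- data.frame(
      replicate = i, group = grp,
      fixed_syn = mk$fixed_syn, fixed_nonsyn = mk$fixed_nonsyn,
      poly_syn = mk$poly_syn, poly_nonsyn = mk$poly_nonsyn,
      mk_2x2_p = fisher_exact_2x2(as.matrix(mk)),
      pairwise_divergence = mean_pairwise_divergence(run$samples[[grp]]))
    om_rows[[length(om_rows) + 1]] <- data.frame(
      replicate = i, group = grp,
      omega_mean = om$omega_mean, omega_se = om$omega_se,
      n_haplotypes = om$n_used)
  }
  if (i == 1) {
    seqs <- DNAStringSet(c(
      GMRCA = decode_seqs(matrix(gmrca, 1)),
      founder = decode_seqs(matrix(run$founder, 1)),
      setNames(decode_seqs(run$samples$mimetic),
               paste0("mimetic_", seq_len(nrow(run$samples$mimetic)))),
      setNames(decode_seqs(run$samples$nonmimetic),
               paste0("nonmimetic_", seq_len(nrow(run$samples$nonmimetic))))))
    writeXStringSet(seqs, "results/dsx_simulated_rep1.fasta")
  }
}
mk_tab <- do.call(rbind, rows)
write.table(mk_tab, "results/mk_tables.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
write.table(do.call(rbind, om_rows), "results/omega_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

message("Per-replicate MK tables (fixed/polymorphic x syn/nonsyn):")
print(mk_tab, row.names = FALSE)

# 4x2 comparison of the two haplotype classes, per replicate
for (i in seq_len(reps)) {
  a <- mk_tab[mk_tab$replicate == i & mk_tab$group == "mimetic", 3:6]
  b <- mk_tab[mk_tab$replicate == i & mk_tab$group == "nonmimetic", 3:6]
  p <- fisher_exact_rxc(cbind(mimetic = as.numeric(a),
                              nonmimetic = as.numeric(b)))
  message(sprintf("  replicate %d: mimetic vs non-mimetic 4x2 exact p = %.4g",
                  i, as.numeric(p)))
}
message("Interpretation: the founder event fixes the standing variants it ",
        "captures, so mimetic samples show more fixed (syn and nonsyn) ",
        "differences and less internal diversity than non-mimetic samples, ",
        "without any MK-style excess of fixed nonsynonymous variation.")
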