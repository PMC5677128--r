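# Independent brute-force oracles. These deliberately re-derive results by
# plain enumeration, sharing no code path with the package implementations.

# two-sided Fisher p for a 2x2 table by explicit enumeration of every table
# with the observed margins, probabilities from factorials
oracle_fisher_2x2 <- function(tab) {
  r <- rowSums(tab); k <- colSums(tab); n <- sum(tab)
  if (any(r == 0) || any(k == 0)) return(1)
  lprob <- function(x11) {
    x12 <- r[1] - x11; x21 <- k[1] - x11; x22 <- r[2] - x21
    if (min(x12, x21, x22) < 0) return(-Inf)
    sum(lfactorial(r)) + sum(lfactorial(k)) - lfactorial(n) -
      sum(lfactorial(c(x11, x12, x21, x22)))
  }
  lp <- vapply(0:min(r[1], k[1]), lprob, numeric(1))
  obs <- lprob(tab[1, 1])
  sum(exp(lp[lp <= obs + 1e-7]))
}

# Benjamini-Hochberg step-up, written out literally
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest rank down
  for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# translation for the brute-force MK recount (independent of the package's
# integer codon indexing): works on character codons via Biostrings
oracle_translate <- function(codon) {
  unname(Biostrings::GENETIC_CODE[[codon]])
}

# site-by-site, frequency-by-frequency MK recount on character matrices
oracle_classify <- function(seqs, anc, maf = 0.05) {
  chars <- do.call(rbind, strsplit(seqs, ""))
  anc_ch <- strsplit(anc, "")[[1]]
  out <- c(fixed_syn = 0, fixed_nonsyn = 0, poly_syn = 0, poly_nonsyn = 0)
  for (s in seq_along(anc_ch)) {
    col <- chars[, s]
    col <- col[col %in% c("A", "C", "G", "T")]
    if (!length(col)) next
    cod_start <- 3 * ((s - 1) %/% 3) + 1
    anc_codon <- paste(anc_ch[cod_start:(cod_start + 2)], collapse = "")
    for (al in setdiff(unique(col), anc_ch[s])) {
      f <- sum(col == al) / length(col)
      der_codon <- anc_codon
      substr(der_codon, (s - 1) %% 3 + 1, (s - 1) %% 3 + 1) <- al
      syn <- oracle_translate(der_codon) == oracle_translate(anc_codon)
      cls <- if (f >= 1 - maf) "fixed" else if (f >= maf) "poly" else next
      key <- paste0(cls, if (syn) "_syn" else "_nonsyn")
      out[key] <- out[key] + 1
    }
  }
  out
}

# plain per-site scan for morph-specific sites on raw matrices
oracle_morph_scan <- function(alleles, positions, tgt_rows, ref_rows,
                              max_exc_tgt = 0, max_exc_ref = 0) {
  hits <- integer()
  for (s in seq_len(ncol(alleles))) {
    tgt <- alleles[tgt_rows, s]
    ref <- alleles[ref_rows, s]
    ok <- FALSE
    for (al in unique(tgt[!is.na(tgt)])) {
      n_exc <- sum(is.na(tgt)) + sum(tgt != al, na.rm = TRUE)
      n_ref <- sum(ref == al, na.rm = TRUE)
      if (n_exc <= max_exc_tgt && n_ref <= max_exc_ref) ok <- TRUE
    }
    if (ok) hits <- c(hits, positions[s])
  }
  hits
}

# weighted single-nucleotide neighbour enumeration on a character string
# (independent of the package's integer-coded version)
oracle_ns_opportunity <- function(seq_str, kappa = 2, site_rates = NULL) {
  ch <- strsplit(seq_str, "")[[1]]
  L <- length(ch) / 3
  if (is.null(site_rates)) site_rates <- rep(1, L)
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  syn <- nonsyn <- 0
  for (s in seq_along(ch)) {
    cod_i <- (s - 1) %/% 3
    codon <- paste(ch[(3 * cod_i + 1):(3 * cod_i + 3)], collapse = "")
    for (new in setdiff(c("A", "C", "G", "T"), ch[s])) {
      w <- (if (new == transitions[[ch[s]]]) kappa else 1) * site_rates[cod_i + 1]
      der <- codon
      substr(der, (s - 1) %% 3 + 1, (s - 1) %% 3 + 1) <- new
      aa <- oracle_translate(der)
      if (aa == "*") next
      if (aa == oracle_translate(codon)) syn <- syn + w else nonsyn <- nonsyn + w
    }
  }
  c(syn = syn, nonsyn = nonsyn)
}
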