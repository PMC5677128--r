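#' Classify coding variation against a known ancestor
#'
#' Builds the McDonald-Kreitman style table of fixed and polymorphic
#' synonymous and non-synonymous changes. Per nucleotide site, every
#' derived allele (different from the ancestor) is placed by its sample
#' frequency `f` among non-missing calls: `f >= 1 - maf_cutoff` counts as
#' fixed, `maf_cutoff <= f < 1 - maf_cutoff` as polymorphic, and rarer
#' alleles are ignored as noise — the same cutoff governs both categories.
#' Each counted change is classified synonymous or non-synonymous in its
#' codon context, holding the other two codon positions at their ancestral
#' state.
#'
#' @param sample Character vector of aligned sequences, or integer matrix
#'   (haplotypes x sites, A=1..T=4, `NA` = missing). At least 2 haplotypes.
#' @param ancestor Ancestral sequence (string or integer vector), same
#'   length, divisible by 3.
#' @param maf_cutoff Minor-allele-frequency threshold (default 0.05).
#' @return Object of class `mk_table`: counts `fixed_syn`, `fixed_nonsyn`,
#'   `poly_syn`, `poly_nonsyn`, plus `maf_cutoff` and `n_haplotypes`.
#' @export
classify_sites <- function(sample, ancestor, maf_cutoff = 0.05) {
  if (is.character(sample)) sample <- encode_seqs(sample)
  if (is.character(ancestor)) ancestor <- as.integer(encode_seqs(ancestor)[1, ])
  stopifnot(nrow(sample) >= 2, ncol(sample) == length(ancestor),
            length(ancestor) %% 3 == 0)
  aa64 <- .aa64()
  fs <- fn <- ps <- pn <- 0L
  for (s in seq_along(ancestor)) {
    col <- sample[, s]
    col <- col[!is.na(col)]
    if (!length(col)) next
    anc <- ancestor[s]
    derived <- setdiff(unique(col), anc)
    if (!length(derived)) next
    cod <- (s - 1L) %/% 3L
    within <- s - 3L * cod
    c123 <- ancestor[(3L * cod + 1L):(3L * cod + 3L)]
    aa_anc <- aa64[(c123[1] - 1L) * 16L + (c123[2] - 1L) * 4L + c123[3]]
    for (d in derived) {
      f <- mean(col == d)
      if (f < maf_cutoff) next
      cn <- c123
      cn[within] <- d
      aa_d <- aa64[(cn[1] - 1L) * 16L + (cn[2] - 1L) * 4L + cn[3]]
      synonymous <- (aa_d == aa_anc)
      if (f >= 1 - maf_cutoff) {
        if (synonymous) fs <- fs + 1L else fn <- fn + 1L
      } else {
        if (synonymous) ps <- ps + 1L else pn <- pn + 1L
      }
    }
  }
  structure(list(fixed_syn = fs, fixed_nonsyn = fn,
                 poly_syn = ps, poly_nonsyn = pn,
                 maf_cutoff = maf_cutoff, n_haplotypes = nrow(sample)),
            class = "mk_table")
}

#' @export
print.mk_table <- function(x, ...) {
  cat(sprintf("MK table (n = %d haplotypes, MAF cutoff %g):\n",
              x$n_haplotypes, x$maf_cutoff))
  print(as.matrix(x))
  invisible(x)
}

#' @export
as.matrix.mk_table <- function(x, ...) {
  matrix(c(x$fixed_syn, x$fixed_nonsyn, x$poly_syn, x$poly_nonsyn),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("fixed", "polymorphic"),
                         c("synonymous", "non-synonymous")))
}

# log multivariate hypergeometric probability of a table with fixed margins
.log_table_prob <- function(tab) {
  n <- sum(tab)
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(n + 1) - sum(lgamma(tab + 1))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by the probability method: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' of outcomes at most as probable as the observed table. A table with a
#' zero margin is degenerate and returns p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0), all(tab == round(tab)))
  m <- rowSums(tab); k <- colSums(tab)
  if (any(m == 0) || any(k == 0)) return(1)
  # cell (1,1) ranges over the hypergeometric support
  support <- max(0, k[1] - m[2]):min(k[1], m[1])
  logp <- stats::dhyper(support, m[1], m[2], k[1], log = TRUE)
  obs <- stats::dhyper(tab[1, 1], m[1], m[2], k[1], log = TRUE)
  sum(exp(logp[logp <= obs + 1e-7]))
}

# recursively enumerate all r x c tables with the given margins, calling
# fun(tab) for each; aborts (returns FALSE) if more than max_tables visited
.enumerate_tables <- function(rows, cols, fun, max_tables = 1e7) {
  r <- length(rows); cc <- length(cols)
  tab <- matrix(0L, r, cc)
  count <- 0L
  rec <- function(i, j, row_left, col_left) {
    if (count > max_tables) return(FALSE)
    if (i == r) {            # last row fully determined
      if (any(col_left < 0)) return(TRUE)
      tab[r, ] <<- col_left
      count <<- count + 1L
      fun(tab)
      return(TRUE)
    }
    if (j == cc) {           # last cell of row i determined
      if (row_left > col_left[cc]) return(TRUE)
      tab[i, cc] <<- row_left
      col_left[cc] <- col_left[cc] - row_left
      return(rec(i + 1L, 1L, rows[i + 1L], col_left))
    }
    for (v in 0:min(row_left, col_left[j])) {
      tab[i, j] <<- v
      cl <- col_left; cl[j] <- cl[j] - v
      if (!rec(i, j + 1L, row_left - v, cl)) return(FALSE)
    }
    TRUE
  }
  ok <- rec(1L, 1L, rows[1L], cols)
  list(ok = ok, count = count)
}

#' Two-sided Fisher exact test for an r x c table
#'
#' Exact p by full enumeration of all tables with the observed margins
#' (probability method) when the enumeration is tractable; otherwise a
#' Monte-Carlo estimate from margin-preserving draws (Patefield's
#' algorithm via [stats::r2dtable()]), with the standard error attached as
#' attribute `"se"`. The method used is attached as attribute `"method"`.
#'
#' @param tab r x c matrix of non-negative integer counts, `r*c <= 32`.
#' @param max_tables Enumeration cap before switching to Monte-Carlo.
#' @param n_mc Number of Monte-Carlo tables.
#' @return p-value in (0, 1].
#' @export
fisher_exact_rxc <- function(tab, max_tables = 1e7, n_mc = 1e5) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), all(tab == round(tab)), length(tab) <= 32)
  if (sum(tab) == 0) return(structure(1, method = "degenerate"))
  rows <- rowSums(tab); cols <- colSums(tab)
  keep_r <- rows > 0; keep_c <- cols > 0
  tab <- tab[keep_r, keep_c, drop = FALSE]
  rows <- rows[keep_r]; cols <- cols[keep_c]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(structure(1, method = "degenerate"))
  log_obs <- .log_table_prob(tab)
  acc <- new.env()
  acc$p <- 0
  res <- .enumerate_tables(rows, cols, function(t) {
    lp <- .log_table_prob(t)
    if (lp <= log_obs + 1e-7) acc$p <- acc$p + exp(lp)
  }, max_tables)
  if (res$ok) return(structure(min(1, acc$p), method = "enumeration",
                               n_tables = res$count))
  draws <- stats::r2dtable(n_mc, rows, cols)
  hits <- vapply(draws, function(t) .log_table_prob(t) <= log_obs + 1e-7,
                 logical(1))
  p <- mean(hits)
  structure(p, method = "monte-carlo", se = sqrt(p * (1 - p) / n_mc))
}

# NG86 synonymous site fraction per position of one codon (by codon id parts)
.ng86_codon_sites <- function(c123, aa64) {
  aa0 <- aa64[(c123[1] - 1L) * 16L + (c123[2] - 1L) * 4L + c123[3]]
  s <- 0
  for (pos in 1:3) {
    for (new in (1:4)[-c123[pos]]) {
      cn <- c123
      cn[pos] <- new
      aa <- aa64[(cn[1] - 1L) * 16L + (cn[2] - 1L) * 4L + cn[3]]
      if (aa == aa0) s <- s + 1 / 3
    }
  }
  s
}

# classify the nucleotide differences between two codons by equal-weighted
# shortest mutational pathways; pathways through stop codons are dropped
# unless all pathways hit a stop. Returns c(syn, nonsyn).
.ng86_codon_diffs <- function(ca, cb, aa64) {
  diff_pos <- which(ca != cb)
  nd <- length(diff_pos)
  if (nd == 0) return(c(0, 0))
  aa_of <- function(x) aa64[(x[1] - 1L) * 16L + (x[2] - 1L) * 4L + x[3]]
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  tallies <- list()
  for (ord in perms(diff_pos)) {
    cur <- ca
    syn <- nonsyn <- 0
    blocked <- FALSE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- cb[pos]
      a0 <- aa_of(cur); a1 <- aa_of(nxt)
      if (a1 == "*") blocked <- TRUE  # endpoints are stop-free, so this is an intermediate
      if (a0 == a1) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    tallies[[length(tallies) + 1]] <- c(syn = syn, nonsyn = nonsyn,
                                        blocked = blocked)
  }
  m <- do.call(rbind, tallies)
  use <- m[, "blocked"] == 0
  if (!any(use)) use <- rep(TRUE, nrow(m))
  c(mean(m[use, "syn"]), mean(m[use, "nonsyn"]))
}

#' Pairwise Ka/Ks by the Nei-Gojobori counting method
#'
#' Synonymous and non-synonymous site counts per codon are averaged between
#' the two sequences; observed differences are classified via equal-weighted
#' shortest mutational pathways; the Jukes-Cantor correction
#' `d = -3/4 log(1 - 4p/3)` is applied to each proportion. Changes to stop
#' codons count as non-synonymous for site counting and pathways through
#' stop codons are excluded where possible.
#'
#' @param seq,ancestor Equal-length stop-free coding sequences (strings or
#'   integer vectors), length divisible by 3. The estimator is symmetric in
#'   its arguments.
#' @return List of class `kaks_result`: `Ka`, `Ks`, `omega` (`NA` when
#'   `Ks` is 0 or a proportion exceeds the correctable range), plus the
#'   site and difference counts `N`, `S`, `Nd`, `Sd`.
#' @export
ka_ks <- function(seq, ancestor) {
  if (is.character(seq)) seq <- as.integer(encode_seqs(seq)[1, ])
  if (is.character(ancestor)) ancestor <- as.integer(encode_seqs(ancestor)[1, ])
  stopifnot(length(seq) == length(ancestor), length(seq) %% 3 == 0)
  aa64 <- .aa64()
  L <- length(seq) %/% 3L
  S <- 0; Sd <- 0; Nd <- 0
  for (cod in 0:(L - 1)) {
    idx <- (3L * cod + 1L):(3L * cod + 3L)
    ca <- ancestor[idx]; cb <- seq[idx]
    S <- S + (.ng86_codon_sites(ca, aa64) + .ng86_codon_sites(cb, aa64)) / 2
    d <- .ng86_codon_diffs(ca, cb, aa64)
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  N <- 3 * L - S
  jc <- function(p) if (is.nan(p) || p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  Ks <- jc(Sd / S)
  Ka <- jc(Nd / N)
  omega <- if (is.na(Ka) || is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks
  structure(list(Ka = Ka, Ks = Ks, omega = omega, N = N, S = S,
                 Nd = Nd, Sd = Sd),
            class = "kaks_result")
}

#' Mean and standard error of omega across haplotypes
#'
#' [ka_ks()] is computed for every haplotype against the ancestor;
#' haplotypes with undefined omega are excluded (and counted).
#'
#' @param sample Character vector of sequences or integer matrix.
#' @param ancestor Ancestral sequence.
#' @return List: `omega_mean`, `omega_se`, per-haplotype `omega`,
#'   `n_used`, `n_undefined`.
#' @export
omega_summary <- function(sample, ancestor) {
  if (is.character(sample)) sample <- encode_seqs(sample)
  om <- apply(sample, 1, function(h) ka_ks(as.integer(h), ancestor)$omega)
  used <- om[!is.na(om)]
  if (!length(used)) stop("omega undefined for every haplotype")
  se <- if (length(used) > 1) stats::sd(used) / sqrt(length(used)) else 0
  list(omega_mean = mean(used), omega_se = se, omega = om,
       n_used = length(used), n_undefined = sum(is.na(om)))
}

#' Compare an observed MK table with simulated replicates
#'
#' Each simulated table is laid side by side with the observed table as a
#' 4x2 contingency table (four MK categories x observed/simulated) and
#' tested with [fisher_exact_rxc()]. The fraction of replicates that do
#' not differ significantly from the observation (p > alpha) is the
#' scenario's fit statistic.
#'
#' @param observed An `mk_table`.
#' @param simulated List of `mk_table`s (>= 1).
#' @param alpha Significance threshold for the fit fraction (default 0.05).
#' @return List: per-replicate `p`, `fit_fraction`.
#' @export
compare_observed_vs_simulated <- function(observed, simulated, alpha = 0.05) {
  stopifnot(length(simulated) >= 1)
  cells <- function(t) c(t$fixed_syn, t$fixed_nonsyn, t$poly_syn, t$poly_nonsyn)
  p <- vapply(simulated, function(sim) {
    as.numeric(fisher_exact_rxc(cbind(observed = cells(observed),
                                      simulated = cells(sim))))
  }, numeric(1))
  list(p = p, fit_fraction = mean(p > alpha))
}
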