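# Integer sequence encoding: bases A,C,G,T = 1,2,3,4; a codon (b1,b2,b3) has
# id (b1-1)*16 + (b2-1)*4 + b3 in 1..64. The amino-acid lookup is built once
# from the standard genetic code.

.codon_env <- new.env(parent = emptyenv())

.aa64 <- function() {
  if (is.null(.codon_env$aa64)) {
    gc <- Biostrings::GENETIC_CODE
    bases <- c("A", "C", "G", "T")
    ids <- expand.grid(b3 = 1:4, b2 = 1:4, b1 = 1:4)  # varies b3 fastest
    codons <- paste0(bases[ids$b1], bases[ids$b2], bases[ids$b3])
    .codon_env$aa64 <- unname(gc[codons])
  }
  .codon_env$aa64
}

# transition partner and the two transversions for each base 1..4
.TS <- c(3L, 4L, 1L, 2L)
.TV1 <- c(2L, 1L, 2L, 1L)
.TV2 <- c(4L, 3L, 4L, 3L)

#' Encode nucleotide strings as integer matrices and back
#'
#' Bases are coded A=1, C=2, G=3, T=4; anything else becomes `NA`.
#'
#' @param x Character vector of equal-length nucleotide strings.
#' @return `encode_seqs()`: integer matrix, one row per sequence.
#' @export
encode_seqs <- function(x) {
  m <- t(vapply(strsplit(toupper(x), ""), function(ch) {
    match(ch, c("A", "C", "G", "T"))
  }, integer(nchar(x[1]))))
  rownames(m) <- names(x)
  m
}

#' @rdname encode_seqs
#' @param m Integer matrix (rows = sequences) or integer vector.
#' @return `decode_seqs()`: character vector of sequences.
#' @export
decode_seqs <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  apply(m, 1, function(r) paste(c("A", "C", "G", "T")[r], collapse = ""))
}

#' Translate an integer-coded sequence
#'
#' @param s Integer vector (length divisible by 3) coded A=1..T=4.
#' @return Character vector of amino acids (`"*"` = stop).
#' @export
translate_codons <- function(s) {
  stopifnot(length(s) %% 3 == 0)
  b1 <- s[seq(1, length(s), 3)]
  b2 <- s[seq(2, length(s), 3)]
  b3 <- s[seq(3, length(s), 3)]
  .aa64()[(b1 - 1L) * 16L + (b2 - 1L) * 4L + b3]
}

#' Check a sequence for internal stop codons
#'
#' @inheritParams translate_codons
#' @return TRUE if no codon translates to a stop.
#' @export
is_stop_free <- function(s) !any(translate_codons(s) == "*")

#' Mutational opportunity of a sequence
#'
#' Exhaustively enumerates all `3L` single-nucleotide neighbours of a coding
#' sequence and accumulates the proposal weight of synonymous and
#' non-synonymous (non-stop) changes, with transitions weighted `kappa` and
#' each transversion 1, optionally scaled by per-codon rate multipliers.
#' Stop-creating changes are excluded (they are rejected by the mutation
#' process). The expected realized nonsyn:syn mutation ratio of the
#' simulator is `omega * nonsyn / syn`.
#'
#' @param s Integer-coded sequence (length divisible by 3), or a string.
#' @param kappa Transition/transversion rate ratio.
#' @param site_rates Per-codon rate multipliers (default all 1).
#' @return List with weighted totals `syn`, `nonsyn`, `stop` and the ratio
#'   `ns_ratio = nonsyn / syn`.
#' @export
ns_opportunity <- function(s, kappa = 2, site_rates = NULL) {
  if (is.character(s)) s <- as.integer(encode_seqs(s)[1, ])
  L <- length(s) / 3
  if (is.null(site_rates)) site_rates <- rep(1, L)
  stopifnot(length(site_rates) == L)
  aa64 <- .aa64()
  syn <- nonsyn <- stp <- 0
  for (pos in seq_along(s)) {
    cod <- (pos - 1L) %/% 3L
    within <- pos - 3L * cod
    c123 <- s[(3L * cod + 1L):(3L * cod + 3L)]
    aa_old <- aa64[(c123[1] - 1L) * 16L + (c123[2] - 1L) * 4L + c123[3]]
    old <- s[pos]
    for (new in (1:4)[-old]) {
      w <- if (new == .TS[old]) kappa else 1
      w <- w * site_rates[cod + 1L]
      cn <- c123
      cn[within] <- new
      aa_new <- aa64[(cn[1] - 1L) * 16L + (cn[2] - 1L) * 4L + cn[3]]
      if (aa_new == "*") stp <- stp + w
      else if (aa_new == aa_old) syn <- syn + w
      else nonsyn <- nonsyn + w
    }
  }
  list(syn = syn, nonsyn = nonsyn, stop = stp, ns_ratio = nonsyn / syn)
}
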