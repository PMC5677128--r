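#' Phased haplotype matrix
#'
#' Container for a panel of phased haplotypes over ordered SNP sites.
#' Allele codes follow VCF: 0 = reference, 1, 2, ... = alternative alleles,
#' `NA` = missing call. Positions are 1-based VCF coordinates on a single
#' named contig.
#'
#' @param alleles Integer matrix, haplotypes x sites (`NA` = missing).
#' @param positions Strictly increasing integer positions, one per column.
#' @param contig Contig name.
#' @param labels Data frame with one row per haplotype: `haplotype`,
#'   `sample`, and optionally `taxon`, `morph`, `group`.
#' @return Object of class `hap_matrix`.
#' @export
hap_matrix <- function(alleles, positions, contig = "chr_dsx", labels = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  stopifnot(ncol(alleles) == length(positions),
            !is.unsorted(positions, strictly = TRUE))
  if (is.null(labels)) {
    labels <- data.frame(haplotype = paste0("hap", seq_len(nrow(alleles))),
                         sample = NA_character_)
  }
  stopifnot(nrow(labels) == nrow(alleles), "haplotype" %in% names(labels))
  rownames(alleles) <- labels$haplotype
  structure(list(alleles = alleles, positions = as.integer(positions),
                 contig = contig, labels = labels),
            class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("hap_matrix: %d haplotypes x %d sites on %s (%.1f%% missing)\n",
              nrow(x$alleles), ncol(x$alleles), x$contig,
              100 * mean(is.na(x$alleles))))
  if ("group" %in% names(x$labels))
    print(table(x$labels$group))
  invisible(x)
}

# haplotype row indices for a group given as label value(s) or indices
.group_rows <- function(hap, group) {
  if (is.numeric(group)) return(as.integer(group))
  if (!"group" %in% names(hap$labels))
    stop("hap_matrix has no 'group' labels")
  which(hap$labels$group %in% group)
}

#' Read a phased VCF into a haplotype matrix
#'
#' Every diploid sample contributes two haplotype rows (`<sample>_A`,
#' `<sample>_B`). Genotypes must be phased (`|`-separated); an unphased
#' non-missing genotype is an error naming the offending record. Missing
#' genotypes are preserved as `NA`. Biallelic and multiallelic records are
#' accepted.
#'
#' @param path Path to a VCF file.
#' @param labels Optional data frame keyed by `sample` with extra columns
#'   (`taxon`, `morph`, `group`) copied onto both haplotypes of the sample.
#' @return A [hap_matrix()].
#' @export
read_phased_vcf <- function(path, labels = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  pos <- vcfR::getPOS(v)
  contig <- unique(vcfR::getCHROM(v))
  if (length(contig) != 1) stop("expected a single contig")
  gt <- vcfR::extract.gt(v, element = "GT")  # sites x samples
  samples <- colnames(gt)
  n_sites <- nrow(gt)
  out <- matrix(NA_integer_, nrow = 2 * length(samples), ncol = n_sites)
  hap_names <- character(2 * length(samples))
  for (j in seq_along(samples)) {
    g <- gt[, j]
    miss <- is.na(g) | g %in% c(".", ".|.", "./.")
    bad <- !miss & grepl("/", g, fixed = TRUE)
    if (any(bad))
      stop(sprintf("unphased genotype for sample %s at %s:%d",
                   samples[j], contig, pos[which(bad)[1]]))
    parts <- strsplit(g, "|", fixed = TRUE)
    a <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    b <- suppressWarnings(as.integer(vapply(parts, function(x) {
      if (length(x) >= 2) x[2] else NA_character_
    }, "")))
    out[2 * j - 1L, ] <- ifelse(miss, NA_integer_, a)
    out[2 * j, ] <- ifelse(miss, NA_integer_, b)
    hap_names[2 * j - 1L] <- paste0(samples[j], "_A")
    hap_names[2 * j] <- paste0(samples[j], "_B")
  }
  lab <- data.frame(haplotype = hap_names,
                    sample = rep(samples, each = 2))
  if (!is.null(labels)) {
    stopifnot("sample" %in% names(labels))
    lab <- merge(lab, labels, by = "sample", all.x = TRUE, sort = FALSE)
    lab <- lab[match(hap_names, lab$haplotype), ]
  }
  hap_matrix(out, pos, contig, lab)
}

#' Write a haplotype matrix as a phased VCF
#'
#' Haplotype rows are paired in order (rows 1-2 = sample 1, ...), so the
#' matrix must have an even number of rows. Allele code `k` is written as
#' the k-th ALT allele of a synthetic A/C/G/T ladder; `NA` becomes `.`.
#' The output is plain (uncompressed) VCF text, readable by
#' [read_phased_vcf()] (round-trip preserves positions and allele codes).
#'
#' @param hap A [hap_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(hap, path) {
  n_hap <- nrow(hap$alleles)
  if (n_hap %% 2 != 0) stop("need an even number of haplotypes (diploids)")
  samples <- unique(hap$labels$sample)
  if (length(samples) != n_hap / 2 || anyNA(samples))
    samples <- paste0("S", seq_len(n_hap / 2))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", hap$contig),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  ladder <- c("A", "C", "G", "T")
  for (s in seq_along(hap$positions)) {
    col <- hap$alleles[, s]
    n_alt <- max(col, 1L, na.rm = TRUE)
    alt <- paste(rep(ladder, length.out = n_alt + 1L)[-1L], collapse = ",")
    gt <- vapply(seq_len(n_hap / 2), function(j) {
      a <- col[2 * j - 1L]; b <- col[2 * j]
      paste(ifelse(is.na(c(a, b)), ".", c(a, b)), collapse = "|")
    }, "")
    writeLines(paste(c(hap$contig, hap$positions[s], ".", "A", alt, ".",
                       "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Morph-specific SNP sites
#'
#' A site qualifies when the target group carries a common allele — with at
#' most `max_exceptions_target` target haplotypes missing or carrying a
#' different allele — and that allele differs from the allele(s) observed in
#' every reference-group haplotype (up to `max_exceptions_ref` reference
#' carriers; reference missing calls are ignored). When several target
#' alleles satisfy the exception budget, the site qualifies if any of them
#' also passes the reference check (the best-supported one is reported).
#'
#' @param hap A [hap_matrix()].
#' @param target_group,reference_group Group label(s) from
#'   `hap$labels$group`, or haplotype row indices. Must be disjoint and
#'   non-empty.
#' @param max_exceptions_target Exceptional (missing or discordant) target
#'   haplotypes tolerated per site (default 0).
#' @param max_exceptions_ref Reference haplotypes allowed to carry the
#'   target allele (default 0).
#' @return Object of class `morph_site_report`: data frame with `position`,
#'   `allele`, `target_support`, `target_exceptions`, `ref_carriers`;
#'   tolerance settings as attributes.
#' @export
morph_specific_sites <- function(hap, target_group, reference_group,
                                 max_exceptions_target = 0,
                                 max_exceptions_ref = 0) {
  ti <- .group_rows(hap, target_group)
  ri <- .group_rows(hap, reference_group)
  if (!length(ti) || !length(ri)) stop("empty group")
  if (length(intersect(ti, ri))) stop("groups must be disjoint")
  rows <- list()
  for (s in seq_along(hap$positions)) {
    tgt <- hap$alleles[ti, s]
    ref <- hap$alleles[ri, s]
    cand <- sort(unique(tgt[!is.na(tgt)]))
    best <- NULL
    for (al in cand) {
      support <- sum(tgt == al, na.rm = TRUE)
      exceptions <- length(tgt) - support  # missing or different allele
      if (exceptions > max_exceptions_target) next
      ref_carriers <- sum(ref == al, na.rm = TRUE)
      if (ref_carriers > max_exceptions_ref) next
      if (is.null(best) || support > best$support)
        best <- list(allele = al, support = support,
                     exceptions = exceptions, ref_carriers = ref_carriers)
    }
    if (!is.null(best))
      rows[[length(rows) + 1]] <- data.frame(
        position = hap$positions[s], allele = best$allele,
        target_support = best$support,
        target_exceptions = best$exceptions,
        ref_carriers = best$ref_carriers)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(), allele = integer(),
               target_support = integer(), target_exceptions = integer(),
               ref_carriers = integer())
  structure(out, class = c("morph_site_report", "data.frame"),
            max_exceptions_target = max_exceptions_target,
            max_exceptions_ref = max_exceptions_ref,
            contig = hap$contig,
            n_target = length(ti), n_reference = length(ri))
}

#' Intersection of two morph-specific site reports
#'
#' @param report_a,report_b `morph_site_report` objects on the same
#'   coordinate system.
#' @param by_allele Also require the qualifying allele to match?
#' @return Integer vector of shared positions.
#' @export
shared_specific_sites <- function(report_a, report_b, by_allele = FALSE) {
  if (!by_allele) return(intersect(report_a$position, report_b$position))
  key_a <- paste(report_a$position, report_a$allele)
  key_b <- paste(report_b$position, report_b$allele)
  report_a$position[key_a %in% key_b]
}

#' Per-site association between two haplotype groups
#'
#' For every site, alleles are cross-tabulated against group membership
#' (2 x k table over non-missing calls) and tested with the exact test
#' [fisher_exact_rxc()]; sites monomorphic among non-missing calls get
#' p = 1. P-values are then Benjamini-Hochberg adjusted across all tested
#' sites.
#'
#' @param hap A [hap_matrix()].
#' @param group_a,group_b Group labels or haplotype row indices, each
#'   covering at least 2 haplotypes.
#' @return Object of class `association_result`: data frame `position`,
#'   `p`, `q`, with group sizes as attributes.
#' @export
site_association <- function(hap, group_a, group_b) {
  ia <- .group_rows(hap, group_a)
  ib <- .group_rows(hap, group_b)
  stopifnot(length(ia) >= 2, length(ib) >= 2)
  p <- vapply(seq_along(hap$positions), function(s) {
    a <- hap$alleles[ia, s]; b <- hap$alleles[ib, s]
    alleles <- sort(unique(c(a[!is.na(a)], b[!is.na(b)])))
    if (length(alleles) < 2) return(1)
    tab <- rbind(a = vapply(alleles, function(al) sum(a == al, na.rm = TRUE), 0L),
                 b = vapply(alleles, function(al) sum(b == al, na.rm = TRUE), 0L))
    as.numeric(fisher_exact_rxc(tab))
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  structure(data.frame(position = hap$positions, p = p, q = q),
            class = c("association_result", "data.frame"),
            n_a = length(ia), n_b = length(ib))
}
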