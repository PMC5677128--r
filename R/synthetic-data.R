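#' Random stop-free coding sequence
#'
#' Codons are drawn uniformly from the 61 non-stop codons of the standard
#' code; the result serves as a grand most recent common ancestor (GMRCA)
#' for the codon simulator.
#'
#' @param L Number of codons (>= 1).
#' @param seed Optional RNG seed (uses the current stream when NULL).
#' @param start_atg Force the first codon to ATG?
#' @return Integer-coded sequence of length `3 L` (A=1..T=4).
#' @export
generate_gmrca <- function(L, seed = NULL, start_atg = FALSE) {
  stopifnot(L >= 1)
  if (!is.null(seed)) set.seed(seed)
  aa64 <- .aa64()
  ok <- which(aa64 != "*")             # the 61 sense codons
  ids <- sample(ok, L, replace = TRUE)
  b1 <- (ids - 1L) %/% 16L + 1L
  rem <- (ids - 1L) %% 16L
  b2 <- rem %/% 4L + 1L
  b3 <- rem %% 4L + 1L
  s <- as.integer(rbind(b1, b2, b3))
  if (start_atg) s[1:3] <- c(1L, 4L, 3L)  # ATG
  s
}

#' Specification of a synthetic phased haplotype panel
#'
#' Describes a two-haplogroup panel (inversion-like: deep divergence, no
#' recombination between groups) with planted group-specific SNPs and
#' missing calls, emulating phased supergene haplotypes of two morphs.
#'
#' @param n_target,n_reference Haplotypes in the target (e.g. theseus) and
#'   reference (e.g. polytes) groups.
#' @param n_sites Total SNP sites.
#' @param n_planted Number of planted target-specific sites (<= n_sites).
#' @param between_divergence Probability that a background site has
#'   different group major alleles (inversion-like divergence).
#' @param within_beta Shape2 of the Beta(0.5, shape2) distribution of
#'   per-site within-group minor-allele frequencies.
#' @param missing_rate Per-call missing probability (never applied at
#'   planted sites, so the planted truth is exact).
#' @param target_label,reference_label Group labels written to the panel.
#' @param contig Contig name.
#' @param seed RNG seed.
#' @return Object of class `panel_spec`.
#' @export
panel_spec <- function(n_target = 6, n_reference = 2, n_sites = 2000,
                       n_planted = 110, between_divergence = 0.3,
                       within_beta = 10, missing_rate = 0.02,
                       target_label = "theseus", reference_label = "polytes",
                       contig = "chr_dsx", seed = 1L) {
  stopifnot(n_planted <= n_sites, n_target >= 1, n_reference >= 1,
            missing_rate >= 0, missing_rate < 1)
  structure(as.list(environment()), class = "panel_spec")
}

#' Generate a phased haplotype panel with known truth
#'
#' Background sites get independent group major alleles (differing between
#' groups with probability `between_divergence`) plus within-group variation
#' at low minor-allele frequencies; planted sites carry allele 1 in every
#' target haplotype and allele 0 in every reference haplotype with no
#' missing data, so they satisfy the morph-specific predicate exactly.
#' Missing calls are injected at `missing_rate` elsewhere. An even number
#' of haplotypes per group is paired into diploid samples for VCF output.
#'
#' @param spec A [panel_spec()].
#' @return List: `hap` (a [hap_matrix()]) and `truth` (data frame of
#'   planted `position`s and alleles, plus the spec).
#' @export
generate_haplotype_panel <- function(spec) {
  set.seed(spec$seed)
  n_hap <- spec$n_target + spec$n_reference
  positions <- sort(sample.int(10L * spec$n_sites, spec$n_sites))
  planted_idx <- sort(sample.int(spec$n_sites, spec$n_planted))
  tgt_rows <- seq_len(spec$n_target)
  ref_rows <- spec$n_target + seq_len(spec$n_reference)
  m <- matrix(0L, n_hap, spec$n_sites)
  for (s in seq_len(spec$n_sites)) {
    if (s %in% planted_idx) {
      m[tgt_rows, s] <- 1L
      m[ref_rows, s] <- 0L
      next
    }
    tgt_major <- if (stats::runif(1) < spec$between_divergence) 1L else 0L
    maf_t <- stats::rbeta(1, 0.5, spec$within_beta)
    maf_r <- stats::rbeta(1, 0.5, spec$within_beta)
    tgt <- ifelse(stats::runif(spec$n_target) < maf_t, 1L - tgt_major, tgt_major)
    ref <- ifelse(stats::runif(spec$n_reference) < maf_r, 1L, 0L)
    miss_t <- stats::runif(spec$n_target) < spec$missing_rate
    miss_r <- stats::runif(spec$n_reference) < spec$missing_rate
    tgt[miss_t] <- NA_integer_
    ref[miss_r] <- NA_integer_
    m[tgt_rows, s] <- tgt
    m[ref_rows, s] <- ref
  }
  group <- c(rep(spec$target_label, spec$n_target),
             rep(spec$reference_label, spec$n_reference))
  # pair haplotypes into diploid samples within each group where possible
  sample_of <- character(n_hap)
  k <- 0L
  for (g in unique(group)) {
    idx <- which(group == g)
    for (j in seq_along(idx)) {
      if (j %% 2 == 1) k <- k + 1L
      sample_of[idx[j]] <- sprintf("%s_s%02d", g, k)
    }
  }
  labels <- data.frame(haplotype = sprintf("%s_h%02d", group, seq_len(n_hap)),
                       sample = sample_of, group = group)
  hap <- hap_matrix(m, positions, spec$contig, labels)
  truth <- data.frame(position = positions[planted_idx],
                      allele = rep(1L, length(planted_idx)))
  list(hap = hap, truth = truth, spec = spec)
}

#' Specification of a synthetic hyperspectral scene
#'
#' A textured "leaf litter" background with a given reflectance spectrum
#' and an elliptical butterfly region with its own spectrum, under a
#' common illumination scale. The spatial texture is isotropic 1/f
#' amplitude noise applied multiplicatively to the whole scene.
#'
#' @param H,W,B Scene height, width, and number of bands.
#' @param wavelengths Band centres (nm).
#' @param background_spectrum Per-band background reflectance; default a
#'   green-leaf-like Gaussian peaking at 550 nm.
#' @param butterfly_spectrum Per-band butterfly reflectance; default equals
#'   the background (a zero-contrast control).
#' @param texture_amplitude Relative amplitude of the 1/f texture
#'   (0 = noiseless).
#' @param butterfly_axes Ellipse semi-axes as fractions of H and W.
#' @param illumination Global radiance scale.
#' @param seed RNG seed.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(H = 64, W = 64, B = 16,
                       wavelengths = seq(360, 660, length.out = B),
                       background_spectrum = gaussian_spectrum(wavelengths, 550, 60),
                       butterfly_spectrum = background_spectrum,
                       texture_amplitude = 0.2,
                       butterfly_axes = c(0.25, 0.3),
                       illumination = 1, seed = 1L) {
  stopifnot(H > 0, W > 0, B == length(wavelengths),
            length(background_spectrum) == B, length(butterfly_spectrum) == B,
            texture_amplitude >= 0, illumination > 0)
  structure(as.list(environment()), class = "scene_spec")
}

#' Gaussian reflectance spectrum
#'
#' @param wavelengths Wavelength grid (nm).
#' @param peak,sigma Peak location and width (nm).
#' @param base,scale Baseline and peak height.
#' @return Per-band reflectance vector.
#' @export
gaussian_spectrum <- function(wavelengths, peak, sigma, base = 0.05, scale = 1) {
  base + scale * exp(-(wavelengths - peak)^2 / (2 * sigma^2))
}

# isotropic 1/f amplitude noise, zero mean, unit sd
.one_over_f_noise <- function(H, W) {
  white <- matrix(stats::rnorm(H * W), H, W)
  Fw <- stats::fft(white)
  fy <- (0:(H - 1)); fy <- ifelse(fy > H / 2, fy - H, fy) / H
  fx <- (0:(W - 1)); fx <- ifelse(fx > W / 2, fx - W, fx) / W
  fr <- sqrt(outer(fy^2, fx^2, "+"))
  amp <- ifelse(fr > 0, 1 / fr, 0)     # kill DC
  tex <- Re(stats::fft(Fw * amp, inverse = TRUE)) / (H * W)
  (tex - mean(tex)) / stats::sd(tex)
}

#' Generate a hyperspectral scene with known truth
#'
#' @param spec A [scene_spec()].
#' @return List: `cube` (a [hyperspectral_cube()]), `mask` (logical
#'   butterfly mask), and `truth` (programmed percent luminance contrast of
#'   butterfly vs background and the two spectra).
#' @export
generate_scene <- function(spec) {
  set.seed(spec$seed)
  yy <- matrix(seq_len(spec$H), spec$H, spec$W)
  xx <- matrix(seq_len(spec$W), spec$H, spec$W, byrow = TRUE)
  mask <- ((yy - (spec$H + 1) / 2) / (spec$butterfly_axes[1] * spec$H))^2 +
    ((xx - (spec$W + 1) / 2) / (spec$butterfly_axes[2] * spec$W))^2 <= 1
  tex <- if (spec$texture_amplitude > 0) .one_over_f_noise(spec$H, spec$W)
         else matrix(0, spec$H, spec$W)
  field <- pmax(0, 1 + spec$texture_amplitude * tex)
  arr <- array(0, c(spec$H, spec$W, spec$B))
  for (b in seq_len(spec$B)) {
    plane <- spec$illumination * field *
      ifelse(mask, spec$butterfly_spectrum[b], spec$background_spectrum[b])
    arr[, , b] <- plane
  }
  truth <- list(
    luminance_contrast_pct = 100 * (sum(spec$butterfly_spectrum) -
                                      sum(spec$background_spectrum)) /
      sum(spec$background_spectrum),
    background_spectrum = spec$background_spectrum,
    butterfly_spectrum = spec$butterfly_spectrum)
  list(cube = hyperspectral_cube(arr, spec$wavelengths), mask = mask,
       truth = truth, spec = spec)
}

#' Write a deterministic fixture set
#'
#' Writes a small, fully reproducible set of plain-text fixtures: a GMRCA
#' FASTA, a phased panel VCF with a sample-label TSV, a hyperspectral cube
#' band-stack with its mask, a tetrachromat receptor-model CSV, and a
#' manifest listing every file with the seeds used. Two invocations with
#' the same seed produce byte-identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Root seed.
#' @return Data frame manifest (also written as `manifest.tsv`).
#' @export
write_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  # GMRCA
  gmrca <- generate_gmrca(60, seed = seed)
  fa <- file.path(out_dir, "gmrca.fasta")
  x <- Biostrings::DNAStringSet(decode_seqs(matrix(gmrca, nrow = 1)))
  names(x) <- "GMRCA"
  Biostrings::writeXStringSet(x, fa)
  paths <- c(paths, fa)
  # haplotype panel
  panel <- generate_haplotype_panel(panel_spec(
    n_target = 6, n_reference = 2, n_sites = 120, n_planted = 15,
    missing_rate = 0.02, seed = seed + 1L))
  vcf <- file.path(out_dir, "panel.vcf")
  write_phased_vcf(panel$hap, vcf)
  lab <- file.path(out_dir, "panel_labels.tsv")
  utils::write.table(unique(panel$hap$labels[c("sample", "group")]),
                     lab, sep = "\t", row.names = FALSE, quote = FALSE)
  tru <- file.path(out_dir, "panel_truth.tsv")
  utils::write.table(panel$truth, tru, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  paths <- c(paths, vcf, lab, tru)
  # scene
  sc <- generate_scene(scene_spec(H = 24, W = 24, B = 8,
                                  wavelengths = seq(360, 660, length.out = 8),
                                  seed = seed + 2L))
  cb <- file.path(out_dir, "scene_cube.txt")
  write_cube_txt(sc$cube, cb)
  mk <- file.path(out_dir, "scene_mask.txt")
  utils::write.table(sc$mask * 1L, mk, row.names = FALSE, col.names = FALSE)
  paths <- c(paths, cb, mk)
  # receptor model
  rm4 <- receptor_model_tetra(sc$cube$wavelengths)
  rc <- file.path(out_dir, "receptors_tetra.csv")
  lines <- c(paste(c("eta", rm4$eta), collapse = ","),
             paste(c("weber", rep(rm4$weber, length(rm4$eta))), collapse = ","),
             paste(c("wavelength", rm4$names), collapse = ","),
             vapply(seq_along(rm4$wavelengths), function(i)
               paste(c(rm4$wavelengths[i], rm4$sensitivity[i, ]), collapse = ","),
               ""))
  writeLines(lines, rc)
  paths <- c(paths, rc)
  manifest <- data.frame(file = basename(paths),
                         bytes = file.size(paths), seed = seed)
  mf <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, mf, sep = "\t", row.names = FALSE, quote = FALSE)
  manifest
}
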