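make_panel <- function(...) generate_haplotype_panel(panel_spec(...))

test_that("phased VCF round-trips and rejects unphased genotypes", {
  # one sample, one phased site
  h <- hap_matrix(matrix(c(0L, 1L), 2, 1), positions = 101,
                  labels = data.frame(haplotype = c("s1_A", "s1_B"),
                                      sample = "s1"))
  f <- tempfile(fileext = ".vcf")
  write_phased_vcf(h, f)
  h2 <- read_phased_vcf(f)
  expect_identical(dim(h2$alleles), c(2L, 1L))
  expect_identical(unname(h2$alleles[, 1]), c(0L, 1L))
  expect_identical(h2$positions, 101L)

  # synthetic panel with missing and multiallelic codes round-trips
  p <- make_panel(n_target = 6, n_reference = 4, n_sites = 80, n_planted = 9,
                  missing_rate = 0.05, seed = 23)
  p$hap$alleles[3, 7] <- 2L   # make one site multiallelic
  f2 <- tempfile(fileext = ".vcf")
  write_phased_vcf(p$hap, f2)
  lab <- unique(p$hap$labels[c("sample", "group")])
  h3 <- read_phased_vcf(f2, labels = lab)
  expect_identical(unname(h3$alleles), unname(p$hap$alleles))
  expect_identical(h3$positions, p$hap$positions)
  expect_identical(h3$labels$group,
                   lab$group[match(h3$labels$sample, lab$sample)])

  # an unphased record is refused by name
  bad <- readLines(f2)
  i <- grep("^[^#]", bad)[2]
  bad[i] <- sub("(\t[0-9.]+)\\|", "\\1/", bad[i])
  fbad <- tempfile(fileext = ".vcf")
  writeLines(bad, fbad)
  expect_error(read_phased_vcf(fbad), "unphased")
})

test_that("morph-specific filter applies the exception rules exactly", {
  mk_hap <- function(tgt, ref) {
    hap_matrix(matrix(c(tgt, ref), ncol = 1), positions = 500,
               labels = data.frame(
                 haplotype = paste0("h", seq_along(c(tgt, ref))),
                 sample = NA, group = rep(c("t", "r"), c(length(tgt), length(ref)))))
  }
  # perfect separation qualifies at zero tolerance
  r <- morph_specific_sites(mk_hap(c(1L, 1L), c(0L, 0L)), "t", "r", 0)
  expect_identical(r$position, 500L)

  # one discordant target haplotype: excluded at 0, admitted at 1
  h <- mk_hap(c(1L, 0L), c(0L, 0L))
  expect_identical(nrow(morph_specific_sites(h, "t", "r", 0)), 0L)
  r <- morph_specific_sites(h, "t", "r", 1)
  expect_identical(r$allele, 1L)

  # a missing target call counts against the same budget
  h <- mk_hap(c(1L, NA), c(0L, 0L))
  expect_identical(nrow(morph_specific_sites(h, "t", "r", 0)), 0L)
  expect_identical(nrow(morph_specific_sites(h, "t", "r", 1)), 1L)

  expect_error(morph_specific_sites(mk_hap(c(1L, 1L), c(0L, 0L)), "t", "x"),
               "empty")
})

test_that("planted panels are fully recovered and match the brute-force scan", {
  for (cfg in list(list(nt = 2, exc = 0, seed = 31),
                   list(nt = 6, exc = 1, seed = 32))) {
    p <- make_panel(n_target = cfg$nt, n_reference = 2, n_sites = 1200,
                    n_planted = 110, missing_rate = 0.02, seed = cfg$seed)
    rep <- morph_specific_sites(p$hap, "theseus", "polytes", cfg$exc)
    expect_true(all(p$truth$position %in% rep$position))
    oracle <- oracle_morph_scan(p$hap$alleles, p$hap$positions,
                                which(p$hap$labels$group == "theseus"),
                                which(p$hap$labels$group == "polytes"),
                                max_exc_tgt = cfg$exc)
    expect_identical(sort(rep$position), sort(oracle))
  }
})

test_that("a discordant extra target haplotype can only shrink the strict set", {
  p <- make_panel(n_target = 4, n_reference = 2, n_sites = 300, n_planted = 20,
                  missing_rate = 0, seed = 33)
  before <- morph_specific_sites(p$hap, "theseus", "polytes", 0)
  # append a target haplotype equal to a reference haplotype
  a2 <- rbind(p$hap$alleles, p$hap$alleles[5, ])
  lab2 <- rbind(p$hap$labels,
                data.frame(haplotype = "extra", sample = NA, group = "theseus"))
  h2 <- hap_matrix(a2, p$hap$positions, p$hap$contig, lab2)
  after <- morph_specific_sites(h2, "theseus", "polytes", 0)
  expect_true(all(after$position %in% before$position))
})

test_that("report intersections work by position and planted overlaps are exact", {
  pa <- make_panel(n_target = 2, n_reference = 2, n_sites = 200, n_planted = 12,
                   missing_rate = 0, seed = 34)
  ra <- morph_specific_sites(pa$hap, "theseus", "polytes", 0)
  expect_identical(shared_specific_sites(ra, ra), ra$position)

  # two panels on the same coordinates with exactly 7 overlapping plants
  set.seed(35)
  pos <- sort(sample.int(5000, 400))
  plant_a <- pos[1:20]; plant_b <- c(plant_a[1:7], pos[51:63])
  build <- function(planted) {
    n <- 6
    m <- matrix(0L, n + 2, length(pos))
    m[1:n, match(planted, pos)] <- 1L
    hap_matrix(m, pos, labels = data.frame(
      haplotype = paste0("h", 1:(n + 2)), sample = NA,
      group = rep(c("t", "r"), c(n, 2))))
  }
  ra <- morph_specific_sites(build(plant_a), "t", "r", 0)
  rb <- morph_specific_sites(build(plant_b), "t", "r", 0)
  expect_setequal(shared_specific_sites(ra, rb), plant_a[1:7])
})

test_that("association p-values, BH correction, and invariants hold", {
  # perfectly separating site among 10 + 10 haplotypes
  m <- cbind(rep(c(0L, 1L), each = 10), rep(0L, 20), rep(c(0L, 1L), 10))
  h <- hap_matrix(m, positions = c(10, 20, 30),
                  labels = data.frame(haplotype = paste0("h", 1:20),
                                      sample = NA,
                                      group = rep(c("m", "n"), each = 10)))
  res <- site_association(h, "m", "n")
  expect_equal(res$p[1], 2 / choose(20, 10), tolerance = 1e-12)
  expect_identical(res$p[2], 1)              # monomorphic site
  expect_true(all(res$q >= res$p - 1e-15))
  ordered <- res$q[order(res$p)]
  expect_true(all(diff(ordered) >= -1e-15))

  # BH equals the independent step-up oracle (and the hand case)
  expect_equal(oracle_bh(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  set.seed(36)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  expect_equal(res$q, oracle_bh(res$p), tolerance = 1e-12)
})

test_that("label permutation yields no anti-conservative association p-values", {
  p <- make_panel(n_target = 10, n_reference = 10, n_sites = 40, n_planted = 0,
                  between_divergence = 0, missing_rate = 0, seed = 37)
  set.seed(38)
  pool <- unlist(lapply(1:250, function(i) {
    perm <- sample(20)
    h <- hap_matrix(p$hap$alleles[perm, ], p$hap$positions, p$hap$contig,
                    data.frame(haplotype = paste0("h", 1:20), sample = NA,
                               group = rep(c("a", "b"), each = 10)))
    site_association(h, "a", "b")$p
  }))
  # exact-test p-values are discrete and conservative: the empirical CDF
  # must not exceed the uniform CDF beyond sampling slack
  expect_lte(mean(pool <= 0.05), 0.05 + 0.03)
  expect_lte(mean(pool <= 0.2), 0.2 + 0.05)
  expect_gte(mean(pool), 0.45)
})
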