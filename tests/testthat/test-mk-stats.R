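test_that("site classification handles the canonical toy cases", {
  anc <- "ATGGAA"
  # no variation at all
  mk <- classify_sites(c(anc, anc), anc)
  expect_identical(unname(unlist(mk[1:4])), rep(0L, 4))

  # a third-position GGA->GGG change carried by all 20 haplotypes is a
  # fixed synonymous difference (glycine preserved)
  anc2 <- "ATGGGA"
  mk <- classify_sites(rep("ATGGGG", 20), anc2)
  expect_identical(mk$fixed_syn, 1L)
  expect_identical(mk$fixed_nonsyn + mk$poly_syn + mk$poly_nonsyn, 0L)

  # GAA->AAA (Glu->Lys) at frequency 0.5 is one polymorphic non-synonymous
  mk <- classify_sites(c("ATGGAA", "ATGGAA", "ATGAAA", "ATGAAA"), anc)
  expect_identical(mk$poly_nonsyn, 1L)
  expect_identical(mk$fixed_syn + mk$fixed_nonsyn + mk$poly_syn, 0L)

  expect_error(classify_sites(c("ATG", "ATG"), "ATGGAA"))
})

test_that("classification equals a brute-force recount on random alignments", {
  set.seed(14)
  for (i in 1:100) {
    g <- generate_gmrca(6)
    anc <- decode_seqs(matrix(g, 1))
    n <- sample(3:8, 1)
    seqs <- vapply(seq_len(n), function(j) {
      s <- g
      nmut <- sample(0:5, 1)
      if (nmut > 0) {
        pos <- sample(length(s), nmut)
        s[pos] <- vapply(s[pos], function(b) sample((1:4)[-b], 1), 0L)
      }
      decode_seqs(matrix(s, 1))
    }, "")
    mk <- classify_sites(seqs, anc, maf_cutoff = 0.05)
    br <- oracle_classify(seqs, anc, maf = 0.05)
    expect_identical(c(mk$fixed_syn, mk$fixed_nonsyn, mk$poly_syn, mk$poly_nonsyn),
                     unname(as.integer(br)))
  }
})

test_that("lowering the MAF cutoff never shrinks any MK cell", {
  set.seed(15)
  g <- generate_gmrca(40)
  pop <- matrix(rep(g, each = 30), nrow = 30)
  res <- mutate_population(pop, codon_model(omega = 0.5, mu = 3e-3, gamma_K = 1))
  a <- classify_sites(res$pop, g, maf_cutoff = 0.05)
  b <- classify_sites(res$pop, g, maf_cutoff = 0)
  for (cell in c("fixed_syn", "fixed_nonsyn", "poly_syn", "poly_nonsyn"))
    expect_gte(b[[cell]], a[[cell]])
})

test_that("2x2 exact test matches enumeration, conventions, and fisher.test", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2)), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_identical(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), 1)

  set.seed(16)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 4), 2)
    p <- fisher_exact_2x2(tab)
    expect_lt(abs(p - oracle_fisher_2x2(tab)), 1e-12)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-9)
  }

  # hypergeometric probabilities over a fixed-margin family sum to 1
  m <- c(7, 5); k <- c(6, 6)
  probs <- dhyper(max(0, k[1] - m[2]):min(k[1], m[1]), m[1], m[2], k[1])
  expect_lt(abs(sum(probs) - 1), 1e-12)
})

test_that("r x c exact test agrees with the 2x2 path and its Monte-Carlo fallback", {
  set.seed(17)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 3), 2)
    expect_lt(abs(as.numeric(fisher_exact_rxc(tab)) - fisher_exact_2x2(tab)),
              1e-12)
  }

  # a table proportional to its margins is the most probable one: p = 1
  ind <- matrix(c(2, 4, 1, 2), 2, byrow = TRUE)
  expect_equal(as.numeric(fisher_exact_rxc(ind)), 1, tolerance = 1e-12)

  # enumeration and Monte-Carlo agree on a 4x2 design
  tab <- matrix(c(3, 0, 0, 3, 3, 0, 0, 3), nrow = 4, byrow = TRUE)
  p_enum <- fisher_exact_rxc(tab)
  expect_identical(attr(p_enum, "method"), "enumeration")
  set.seed(18)
  p_mc <- fisher_exact_rxc(tab, max_tables = 1, n_mc = 2e4)
  expect_identical(attr(p_mc, "method"), "monte-carlo")
  expect_lt(abs(as.numeric(p_enum) - as.numeric(p_mc)),
            3 * attr(p_mc, "se") + 1e-12)

  expect_identical(as.numeric(fisher_exact_rxc(matrix(0L, 2, 2))), 1)
})

test_that("NG86 Ka/Ks reproduces hand-worked cases and is symmetric", {
  r <- ka_ks("ATGAAA", "ATGAAA")
  expect_identical(r$Ka, 0); expect_identical(r$Ks, 0)
  expect_true(is.na(r$omega))

  # a lone TTT->TTC change is synonymous: Ka = 0, Ks > 0 (the context is
  # long enough to keep the synonymous proportion inside the JC range)
  r <- ka_ks("TTCAAACCCGGGATT", "TTTAAACCCGGGATT")
  expect_identical(r$Ka, 0)
  expect_identical(r$Nd, 0)
  expect_equal(r$Sd, 1)
  expect_gt(r$Ks, 0)

  # worked by hand for ATG TTT vs ATG CTT:
  # sites S = (1/3 + 1)/2 = 2/3, N = 16/3; one nonsyn difference
  r <- ka_ks("ATGTTT", "ATGCTT")
  expect_equal(r$S, 2 / 3, tolerance = 1e-9)
  expect_equal(r$N, 16 / 3, tolerance = 1e-9)
  expect_equal(r$Nd, 1); expect_equal(r$Sd, 0)
  expect_equal(r$Ka, -3 / 4 * log(1 - 4 * (3 / 16) / 3), tolerance = 1e-9)
  expect_identical(r$Ks, 0)

  set.seed(19)
  for (i in 1:20) {
    a <- generate_gmrca(15)
    b <- a
    pos <- sample(length(b), 6)
    b[pos] <- vapply(b[pos], function(x) sample((1:4)[-x], 1), 0L)
    if (!is_stop_free(b)) next
    r1 <- ka_ks(a, b); r2 <- ka_ks(b, a)
    expect_equal(r1$Ka, r2$Ka, tolerance = 1e-12)
    expect_equal(r1$Ks, r2$Ks, tolerance = 1e-12)
  }
})

test_that("omega summaries aggregate per-haplotype values correctly", {
  anc <- "ATGGGATTTAAACCC"
  # identical haplotypes: zero spread
  s <- omega_summary(rep("ATGGGATTTAAACCT", 4), anc)  # CCC->CCT synonymous...
  # all omega equal (here 0): SE must be 0
  expect_identical(s$omega_se, 0)

  # arithmetic on two known per-haplotype values
  h1 <- "ATGGGGTTTAAACCC"   # GGA->GGG synonymous: omega = 0
  h2 <- "ATGGGATTTAAACCA"   # CCC->CCA synonymous: omega = 0
  h3 <- "ATGGGACTTAAACCC"   # TTT->CTT nonsynonymous: omega undefined (Ks=0)
  o2 <- ka_ks(h1, anc)$omega
  expect_identical(o2, 0)
  s <- omega_summary(c(h1, h2, h3), anc)
  expect_identical(s$n_undefined, 1L)
  expect_identical(s$n_used, 2L)
  expect_identical(s$omega_mean, 0)

  expect_error(omega_summary(c(h3, h3), anc), "undefined")
})

test_that("observed-vs-simulated comparison flags mismatched regimes", {
  obs <- structure(list(fixed_syn = 10, fixed_nonsyn = 2, poly_syn = 30,
                        poly_nonsyn = 8), class = "mk_table")
  self <- compare_observed_vs_simulated(obs, list(obs))
  expect_equal(self$p, 1, tolerance = 1e-12)
  expect_identical(self$fit_fraction, 1)

  far <- structure(list(fixed_syn = 2, fixed_nonsyn = 40, poly_syn = 3,
                        poly_nonsyn = 1), class = "mk_table")
  res <- compare_observed_vs_simulated(obs, list(far))
  expect_lt(res$p, 0.01)
})
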