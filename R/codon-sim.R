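#' Codon substitution model
#'
#' Substitution-model parameters for the forward-in-time codon simulator.
#' `omega` acts as an acceptance multiplier on proposed non-synonymous
#' changes (synonymous proposals are always accepted, stop-creating
#' proposals always rejected), giving the usual dN/dS interpretation.
#' Among-site rate variation uses a discrete gamma with `gamma_K`
#' equal-probability categories whose category rates are bin means of the
#' mean-one gamma density (so the categories average exactly 1); each codon
#' is assigned one category, fixed for a run.
#'
#' @param omega Nonsynonymous/synonymous rate ratio, >= 0.
#' @param mu Proposal rate per nucleotide site per generation.
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param gamma_alpha Shape of the discrete gamma (default 0.8).
#' @param gamma_K Number of gamma categories (default 3; 1 disables rate
#'   variation).
#' @return Object of class `codon_model`.
#' @export
codon_model <- function(omega = 0.05, mu = 1.5e-4, kappa = 2,
                        gamma_alpha = 0.8, gamma_K = 3) {
  stopifnot(omega >= 0, mu > 0, kappa > 0, gamma_K >= 1)
  if (gamma_alpha <= 0) stop("gamma_alpha must be > 0")
  structure(list(omega = omega, mu = mu, kappa = kappa,
                 gamma_alpha = gamma_alpha, gamma_K = as.integer(gamma_K)),
            class = "codon_model")
}

#' Discrete-gamma category rates
#'
#' Category rates are the conditional means of a Gamma(shape = alpha,
#' rate = alpha) density over K equal-probability bins; they average
#' exactly 1.
#'
#' @param alpha Gamma shape (> 0).
#' @param K Number of categories.
#' @return Numeric vector of K category rates.
#' @export
discrete_gamma_rates <- function(alpha, K) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (K == 1) return(1)
  edges <- stats::qgamma(seq(0, 1, length.out = K + 1), shape = alpha, rate = alpha)
  # E[X; a<X<b] for Gamma(alpha, alpha) = pgamma(b, alpha+1) - pgamma(a, alpha+1)
  upper <- stats::pgamma(edges[-1], shape = alpha + 1, rate = alpha)
  lower <- stats::pgamma(edges[-(K + 1)], shape = alpha + 1, rate = alpha)
  K * (upper - lower)
}

#' Assign per-codon rate multipliers
#'
#' Each codon draws one of the K discrete-gamma category rates uniformly
#' (equal-probability categories). The assignment is fixed for a run.
#'
#' @param model A [codon_model()].
#' @param L Number of codons.
#' @return Numeric vector of L per-codon multipliers, with the category
#'   index as attribute `"category"`.
#' @export
draw_site_rates <- function(model, L) {
  stopifnot(L >= 1)
  rates <- discrete_gamma_rates(model$gamma_alpha, model$gamma_K)
  cat_idx <- sample.int(model$gamma_K, L, replace = TRUE)
  structure(rates[cat_idx], category = cat_idx)
}

#' Mutate a haplotype population for one generation
#'
#' Proposes per-copy, per-site changes at rate `mu * site_rate`, with the
#' transition weighted `kappa` against the two transversions. A proposal
#' that is synonymous in its current codon context is always realized; a
#' non-synonymous proposal is realized with probability `omega`; proposals
#' creating a stop codon are always rejected. Proposals are applied
#' sequentially so each sees the up-to-date codon context.
#'
#' @param pop Integer matrix (haplotype copies x nucleotide sites, coded
#'   A=1..T=4), number of columns divisible by 3.
#' @param model A [codon_model()].
#' @param site_rates Per-codon rate multipliers (default all 1), e.g. from
#'   [draw_site_rates()].
#' @return List with the mutated `pop` and `counts`: named vector of
#'   `proposed`, `syn`, `nonsyn`, `rejected_omega`, `rejected_stop`.
#' @export
mutate_population <- function(pop, model, site_rates = NULL) {
  n <- nrow(pop); nsites <- ncol(pop)
  stopifnot(nsites %% 3 == 0)
  L <- nsites %/% 3L
  if (is.null(site_rates)) site_rates <- rep(1, L)
  rate_nt <- rep(site_rates, each = 3) * model$mu
  n_prop <- stats::rpois(1L, n * sum(rate_nt))
  syn <- nonsyn <- rej_o <- rej_s <- 0L
  if (n_prop > 0) {
    aa64 <- .aa64()
    rows <- sample.int(n, n_prop, replace = TRUE)
    sites <- sample.int(nsites, n_prop, replace = TRUE, prob = rate_nt)
    is_ts <- stats::runif(n_prop) < model$kappa / (model$kappa + 2)
    tv_pick <- stats::runif(n_prop) < 0.5
    u_acc <- stats::runif(n_prop)
    for (k in seq_len(n_prop)) {
      i <- rows[k]; s <- sites[k]
      old <- pop[i, s]
      new <- if (is_ts[k]) .TS[old] else if (tv_pick[k]) .TV1[old] else .TV2[old]
      cod <- (s - 1L) %/% 3L
      within <- s - 3L * cod
      j <- 3L * cod
      c1 <- pop[i, j + 1L]; c2 <- pop[i, j + 2L]; c3 <- pop[i, j + 3L]
      aa_old <- aa64[(c1 - 1L) * 16L + (c2 - 1L) * 4L + c3]
      if (within == 1L) c1 <- new else if (within == 2L) c2 <- new else c3 <- new
      aa_new <- aa64[(c1 - 1L) * 16L + (c2 - 1L) * 4L + c3]
      if (aa_new == "*") {
        rej_s <- rej_s + 1L
      } else if (aa_new == aa_old) {
        pop[i, s] <- new; syn <- syn + 1L
      } else if (u_acc[k] < model$omega) {
        pop[i, s] <- new; nonsyn <- nonsyn + 1L
      } else {
        rej_o <- rej_o + 1L
      }
    }
  }
  list(pop = pop,
       counts = c(proposed = n_prop, syn = syn, nonsyn = nonsyn,
                  rejected_omega = rej_o, rejected_stop = rej_s))
}

#' One Wright-Fisher generation of a haplotype population
#'
#' Offspring choose parents uniformly with replacement; with probability
#' `r * (sites - 1)` an offspring is a recombinant splice of two parents at
#' a uniform breakpoint; mutation then applies via [mutate_population()].
#'
#' @inheritParams mutate_population
#' @param size_next Population size of the next generation (>= 1).
#' @param r Recombination rate per adjacent site pair per generation.
#' @return List with `pop` (size_next x sites) and mutation `counts`.
#' @export
wright_fisher_generation <- function(pop, size_next, model, r = 0,
                                     site_rates = NULL) {
  stopifnot(size_next >= 1)
  n <- nrow(pop); nsites <- ncol(pop)
  parents <- sample.int(n, size_next, replace = TRUE)
  off <- pop[parents, , drop = FALSE]
  if (r > 0 && n > 1 && nsites > 1) {
    p_rec <- min(1, r * (nsites - 1))
    rec <- which(stats::runif(size_next) < p_rec)
    for (i in rec) {
      mate <- sample.int(n, 1L)
      brk <- sample.int(nsites - 1L, 1L)  # crossover after column brk
      off[i, (brk + 1L):nsites] <- pop[mate, (brk + 1L):nsites]
    }
  }
  mutate_population(off, model, site_rates)
}

#' Scenario specification for the codon simulator
#'
#' `"nonmimetic-constant"` is a single constant-size population evolving
#' from the GMRCA under purifying selection. `"mimetic-two-phase"` adds a
#' second phase: one haplotype drawn uniformly from the end of phase 1
#' founds a new (mimetic) population that grows logistically from the
#' single founder to `N_m` over `growth_generations`, then stays constant,
#' while the phase-1 (non-mimetic) population keeps evolving in parallel;
#' both populations are sampled at the end.
#'
#' @param preset `"nonmimetic-constant"` or `"mimetic-two-phase"`.
#' @param N Phase-1 (non-mimetic) population size, haploid copies.
#' @param N_m Mimetic population size after growth (default `N`).
#' @param phase1_generations,phase2_generations Phase durations.
#' @param growth_generations Generations of logistic growth from the single
#'   founder to `N_m` (default 10% of phase 2).
#' @param model A [codon_model()].
#' @param r Recombination rate per adjacent site pair per generation.
#' @param sample_size Haplotypes sampled per terminal population.
#' @return Object of class `codon_scenario`.
#' @export
codon_scenario <- function(preset = c("mimetic-two-phase", "nonmimetic-constant"),
                           N = 500, N_m = N,
                           phase1_generations = 1000,
                           phase2_generations = 50,
                           growth_generations = max(1L, round(0.1 * phase2_generations)),
                           model = codon_model(), r = 0, sample_size = 20) {
  preset <- match.arg(preset)
  stopifnot(phase1_generations >= 0, phase2_generations >= 0,
            N >= 1, N_m >= 1, sample_size >= 1)
  if (sample_size > N || (preset == "mimetic-two-phase" && sample_size > N_m))
    stop("sample_size exceeds a population size at sampling time")
  structure(list(preset = preset, N = N, N_m = N_m,
                 phase1_generations = as.integer(phase1_generations),
                 phase2_generations = as.integer(phase2_generations),
                 growth_generations = as.integer(growth_generations),
                 model = model, r = r, sample_size = as.integer(sample_size)),
            class = "codon_scenario")
}

.logistic_sizes <- function(K, G) {
  if (K == 1) return(rep(1L, G))
  g <- log(2 * K * (K - 1)) / G
  t <- seq_len(G)
  pmin(K, pmax(1L, as.integer(round(K / (1 + (K - 1) * exp(-g * t))))))
}

#' Run a codon-evolution scenario
#'
#' Burns a population of identical GMRCA copies through phase 1; for
#' two-phase scenarios a random phase-1 haplotype then founds the mimetic
#' population (genetic hitchhiking: every variant on the founder is carried
#' to high frequency by the expansion), which grows and evolves alongside
#' the continuing non-mimetic population through phase 2. Terminal samples
#' are drawn without replacement.
#'
#' @param spec A [codon_scenario()].
#' @param gmrca Integer-coded ancestral sequence (or string), stop-free,
#'   length divisible by 3.
#' @param site_rates Per-codon rate multipliers; by default drawn once via
#'   [draw_site_rates()] and shared by both populations.
#' @return List of class `codon_sim_sample`: `samples` (list of integer
#'   matrices `nonmimetic` and, for two-phase runs, `mimetic`), `gmrca`,
#'   `founder` (NULL for single-phase), `site_rates`, `spec`, and realized
#'   mutation `counts`.
#' @export
run_scenario <- function(spec, gmrca, site_rates = NULL) {
  if (is.character(gmrca)) gmrca <- as.integer(encode_seqs(gmrca)[1, ])
  stopifnot(length(gmrca) %% 3 == 0)
  if (!is_stop_free(gmrca)) stop("GMRCA contains an internal stop codon")
  L <- length(gmrca) %/% 3L
  if (is.null(site_rates)) site_rates <- draw_site_rates(spec$model, L)
  counts <- c(proposed = 0, syn = 0, nonsyn = 0,
              rejected_omega = 0, rejected_stop = 0)
  pop <- matrix(rep(gmrca, each = spec$N), nrow = spec$N)
  for (g in seq_len(spec$phase1_generations)) {
    step <- wright_fisher_generation(pop, spec$N, spec$model, spec$r, site_rates)
    pop <- step$pop; counts <- counts + step$counts
  }
  founder <- NULL
  mim <- NULL
  if (spec$preset == "mimetic-two-phase" && spec$phase2_generations > 0) {
    founder <- pop[sample.int(nrow(pop), 1L), ]
    sizes <- c(.logistic_sizes(spec$N_m, spec$growth_generations),
               rep(spec$N_m, max(0L, spec$phase2_generations - spec$growth_generations)))
    mim <- matrix(founder, nrow = 1)
    for (g in seq_len(spec$phase2_generations)) {
      step <- wright_fisher_generation(mim, sizes[g], spec$model, spec$r, site_rates)
      mim <- step$pop; counts <- counts + step$counts
      step <- wright_fisher_generation(pop, spec$N, spec$model, spec$r, site_rates)
      pop <- step$pop; counts <- counts + step$counts
    }
  }
  take <- function(m) m[sample.int(nrow(m), spec$sample_size), , drop = FALSE]
  samples <- list(nonmimetic = take(pop))
  if (!is.null(mim)) samples$mimetic <- take(mim)
  structure(list(samples = samples, gmrca = gmrca, founder = founder,
                 site_rates = site_rates, spec = spec, counts = counts),
            class = "codon_sim_sample")
}

#' Mean pairwise nucleotide divergence within a sample
#'
#' Proportion of differing sites, averaged over all haplotype pairs.
#'
#' @param sample Integer matrix (haplotypes x sites).
#' @return Scalar mean pairwise difference per site.
#' @export
mean_pairwise_divergence <- function(sample) {
  n <- nrow(sample)
  stopifnot(n >= 2)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    tot <- tot + mean(sample[i, ] != sample[j, ])
  tot / (n * (n - 1) / 2)
}
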