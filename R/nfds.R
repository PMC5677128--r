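#' Parameters for the NFDS + drift model
#'
#' Bundles the parameters of the modified negative frequency-dependent
#' selection (NFDS) model of mimicry polymorphism. Genotype fitnesses are
#' \deqn{w_{mm} = a(1 - z f_{mm} - z f_{mn})}
#' \deqn{w_{mn} = b(1 - z f_{mm} - z f_{mn})}
#' \deqn{w_{nn} = 1 - z f_{nn}}
#' where `m` is the mimetic and `n` the non-mimetic allele. NFDS acts on
#' phenotype frequency (mimicry is dominant: the heterozygote is mimetic),
#' while `a` and `b` grant an additional positive-selection benefit to the
#' homozygous-mimetic and heterozygous genotypes.
#'
#' @param z Strength of frequency dependence, in `[0, 1)`. `z < 1` keeps all
#'   fitnesses strictly positive.
#' @param a Fitness multiplier of the homozygous mimetic genotype (>= 0).
#' @param b Fitness multiplier of the heterozygote (>= 0).
#' @param Ne Effective population size (diploid individuals, >= 1); drift
#'   resamples `2 Ne` allele copies each generation.
#' @param p0 Initial mimetic allele frequency in `[0, 1]`.
#' @param n_generations Number of generations to simulate.
#' @param n_runs Number of replicate stochastic runs.
#' @param seed Root RNG seed; replicate `i` uses the child seed `seed + i`.
#' @return An object of class `nfds_params`.
#' @export
#' @examples
#' nfds_params(z = 0.25, a = 2, b = 2, Ne = 100)
nfds_params <- function(z = 0.25, a = 1, b = 1, Ne = 1000, p0 = 0.25,
                        n_generations = 400, n_runs = 10, seed = 1L) {
  stopifnot(is.numeric(z), length(z) == 1, z >= 0, z < 1,
            is.numeric(a), a >= 0, is.numeric(b), b >= 0,
            is.numeric(Ne), Ne >= 1,
            is.numeric(p0), p0 >= 0, p0 <= 1,
            n_generations >= 1, n_runs >= 1)
  structure(list(z = z, a = a, b = b, Ne = Ne, p0 = p0,
                 n_generations = as.integer(n_generations),
                 n_runs = as.integer(n_runs), seed = as.integer(seed)),
            class = "nfds_params")
}

#' Genotype frequencies under Hardy-Weinberg
#'
#' @param p Mimetic allele frequency.
#' @return List with `f_mm`, `f_mn`, `f_nn` (summing to 1).
#' @export
hwe_frequencies <- function(p) {
  q <- 1 - p
  list(f_mm = p * p, f_mn = 2 * p * q, f_nn = q * q)
}

#' Genotype fitnesses under the NFDS model
#'
#' @param freqs List with genotype frequencies `f_mm`, `f_mn`, `f_nn`
#'   (must sum to 1 within 1e-12).
#' @param params An [nfds_params()] object (only `z`, `a`, `b` are used).
#' @return List with `w_mm`, `w_mn`, `w_nn` and the Hardy-Weinberg mean
#'   fitness `w_mean` computed from the supplied frequencies.
#' @export
genotype_fitness <- function(freqs, params) {
  f <- unlist(freqs[c("f_mm", "f_mn", "f_nn")])
  if (any(f < 0) || abs(sum(f) - 1) > 1e-12)
    stop("genotype frequencies must be non-negative and sum to 1")
  mim <- f[["f_mm"]] + f[["f_mn"]]  # mimetic phenotype frequency
  w_mm <- params$a * (1 - params$z * mim)
  w_mn <- params$b * (1 - params$z * mim)
  w_nn <- 1 - params$z * f[["f_nn"]]
  w_mean <- f[["f_mm"]] * w_mm + f[["f_mn"]] * w_mn + f[["f_nn"]] * w_nn
  list(w_mm = w_mm, w_mn = w_mn, w_nn = w_nn, w_mean = w_mean)
}

#' One deterministic generation of the NFDS model
#'
#' Genotypes are formed by random mating (Hardy-Weinberg) from the current
#' allele frequency, selected according to [genotype_fitness()], and the
#' post-selection mimetic allele frequency is returned:
#' \deqn{p' = (p^2 w_{mm} + p q w_{mn}) / \bar W}
#' with \eqn{\bar W = p^2 w_{mm} + 2 p q w_{mn} + q^2 w_{nn}}, so that
#' `p' + q' = 1` exactly and 0 and 1 are absorbing fixed points.
#'
#' @param p Current mimetic allele frequency in `[0, 1]`.
#' @param params An [nfds_params()] object.
#' @return Updated allele frequency `p'`.
#' @export
deterministic_step <- function(p, params) {
  stopifnot(p >= 0, p <= 1)
  if (p == 0 || p == 1) return(p)
  q <- 1 - p
  f <- hwe_frequencies(p)
  w <- genotype_fitness(f, params)
  (p * p * w$w_mm + p * q * w$w_mn) / w$w_mean
}

#' One Wright-Fisher generation with selection
#'
#' Applies [deterministic_step()] and then resamples `2 Ne` allele copies
#' binomially (genetic drift).
#'
#' @inheritParams deterministic_step
#' @return Allele frequency `k / (2 Ne)` for a binomial draw `k`.
#' @export
wright_fisher_step <- function(p, params) {
  if (params$Ne < 1) stop("Ne must be >= 1")
  p_det <- deterministic_step(p, params)
  if (p_det <= 0 || p_det >= 1) return(round(p_det))
  n2 <- round(2 * params$Ne)
  stats::rbinom(1L, n2, p_det) / n2
}

#' Simulate one stochastic trajectory
#'
#' @inheritParams deterministic_step
#' @param keep_trajectory Keep the per-generation frequency vector?
#' @return List with `p_final`, `state` (one of `"segregating"`,
#'   `"fixed_mimetic"`, `"lost_mimetic"`), and optionally `trajectory`
#'   (length `n_generations + 1`, starting at `p0`; absorbing states are
#'   padded so the trajectory stays at 0 or 1 once reached).
#' @export
nfds_trajectory <- function(params, keep_trajectory = FALSE) {
  p <- params$p0
  traj <- if (keep_trajectory) numeric(params$n_generations + 1L) else NULL
  if (keep_trajectory) traj[1L] <- p
  for (g in seq_len(params$n_generations)) {
    if (p > 0 && p < 1) p <- wright_fisher_step(p, params)
    if (keep_trajectory) traj[g + 1L] <- p
  }
  state <- if (p == 1) "fixed_mimetic" else if (p == 0) "lost_mimetic" else "segregating"
  list(p_final = p, state = state, trajectory = traj)
}

#' Replicate runs and fixation summary
#'
#' Runs `n_runs` independent Wright-Fisher trajectories (child seed
#' `seed + i` for run `i`) and tallies terminal states after the fixed
#' horizon `n_generations`; runs still polymorphic are reported as
#' segregating rather than forced to absorption.
#'
#' @param params An [nfds_params()] object.
#' @param keep_trajectories Keep all per-run trajectories?
#' @return List of class `fixation_summary`: counts `fixed`, `lost`,
#'   `segregating`, the fixation frequency `fixed / n_runs`, and
#'   `trajectories` (NULL unless requested).
#' @export
run_replicates <- function(params, keep_trajectories = FALSE) {
  states <- character(params$n_runs)
  trajs <- if (keep_trajectories) vector("list", params$n_runs) else NULL
  for (i in seq_len(params$n_runs)) {
    set.seed(params$seed + i)
    res <- nfds_trajectory(params, keep_trajectory = keep_trajectories)
    states[i] <- res$state
    if (keep_trajectories) trajs[[i]] <- res$trajectory
  }
  fixed <- sum(states == "fixed_mimetic")
  lost <- sum(states == "lost_mimetic")
  seg <- sum(states == "segregating")
  structure(list(fixed = fixed, lost = lost, segregating = seg,
                 n_runs = params$n_runs,
                 fixation_frequency = fixed / params$n_runs,
                 trajectories = trajs, params = params),
            class = "fixation_summary")
}

#' Deterministic equilibrium of the NFDS map
#'
#' Iterates [deterministic_step()] from `p0` until `|p' - p| < tol` (or the
#' iteration cap). For pure NFDS (`a = b = 1`) the interior equilibrium is
#' phenotype-frequency parity, `p* = 1 - sqrt(1/2)`, independent of `z`; for
#' `a = b` with an interior equilibrium it satisfies
#' `q*^2 = (1 - a + a z) / (z (a + 1))`.
#'
#' @inheritParams run_replicates
#' @param tol Convergence tolerance on `|p' - p|`.
#' @param max_iter Iteration cap.
#' @return List with `p_star`, `iterations`, `converged`.
#' @export
nfds_equilibrium <- function(params, tol = 1e-12, max_iter = 1e6) {
  p <- params$p0
  for (i in seq_len(max_iter)) {
    p_new <- deterministic_step(p, params)
    if (abs(p_new - p) < tol)
      return(list(p_star = p_new, iterations = i, converged = TRUE))
    p <- p_new
  }
  list(p_star = p, iterations = max_iter, converged = FALSE)
}

#' Parameter sweep over a grid of NFDS scenarios
#'
#' @param grid Data frame with columns `z`, `a`, `b`, `Ne`, `p0` (and
#'   optionally `n_generations`, `n_runs`); one row per parameter set.
#' @param n_generations,n_runs,seed Defaults applied to rows lacking them.
#'   Row `i` of the grid uses root seed `seed + 1000 * i` so rows are
#'   independent and reproducible.
#' @return Data frame: the grid plus `fixed`, `lost`, `segregating`,
#'   `fixation_frequency`.
#' @export
parameter_sweep <- function(grid, n_generations = 400, n_runs = 10, seed = 1L) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1,
            all(c("z", "a", "b", "Ne", "p0") %in% names(grid)))
  if (is.null(grid$n_generations)) grid$n_generations <- n_generations
  if (is.null(grid$n_runs)) grid$n_runs <- n_runs
  out <- grid
  out$fixed <- out$lost <- out$segregating <- NA_integer_
  out$fixation_frequency <- NA_real_
  for (i in seq_len(nrow(grid))) {
    pr <- nfds_params(z = grid$z[i], a = grid$a[i], b = grid$b[i],
                      Ne = grid$Ne[i], p0 = grid$p0[i],
                      n_generations = grid$n_generations[i],
                      n_runs = grid$n_runs[i],
                      seed = seed + 1000L * i)
    s <- run_replicates(pr)
    out$fixed[i] <- s$fixed; out$lost[i] <- s$lost
    out$segregating[i] <- s$segregating
    out$fixation_frequency[i] <- s$fixation_frequency
  }
  out
}

#' Built-in scenario grids
#'
#' `"scenario-grid"` crosses the eight selection scenarios
#' (a=b=1; a=b=1.5,3,5; (a,b) in {(1.5,2),(2,3),(4,5),(1.5,5)}) with
#' z in {0.05,0.25,0.5,0.75,0.95} and p0 in {0.05,0.25,0.5,0.75,0.95}
#' (200 rows) at a single `Ne`. `"fixation-by-Ne"` crosses
#' a=b in {1,1.25,1.5,1.75,2} with Ne in {1e2,1e3,1e4,1e5} at z=0.25,
#' p0=0.25 (the selection-by-drift fixation design).
#'
#' @param preset `"scenario-grid"` or `"fixation-by-Ne"`.
#' @param Ne Effective population size for `"scenario-grid"`.
#' @return Data frame suitable for [parameter_sweep()].
#' @export
nfds_preset_grid <- function(preset = c("scenario-grid", "fixation-by-Ne"),
                             Ne = 1000) {
  preset <- match.arg(preset)
  if (preset == "scenario-grid") {
    ab <- data.frame(a = c(1, 1.5, 3, 5, 1.5, 2, 4, 1.5),
                     b = c(1, 1.5, 3, 5, 2, 3, 5, 5))
    grid <- expand.grid(scenario = seq_len(nrow(ab)),
                        z = c(0.05, 0.25, 0.5, 0.75, 0.95),
                        p0 = c(0.05, 0.25, 0.5, 0.75, 0.95))
    grid$a <- ab$a[grid$scenario]
    grid$b <- ab$b[grid$scenario]
    grid$Ne <- Ne
    grid[c("scenario", "a", "b", "z", "p0", "Ne")]
  } else {
    grid <- expand.grid(ab = c(1, 1.25, 1.5, 1.75, 2),
                        Ne = c(1e2, 1e3, 1e4, 1e5))
    data.frame(a = grid$ab, b = grid$ab, z = 0.25, p0 = 0.25, Ne = grid$Ne)
  }
}

#' @export
print.fixation_summary <- function(x, ...) {
  cat(sprintf(
    "NFDS fixation summary: %d runs (z=%g, a=%g, b=%g, Ne=%g, p0=%g, %d gen)\n",
    x$n_runs, x$params$z, x$params$a, x$params$b, x$params$Ne,
    x$params$p0, x$params$n_generations))
  cat(sprintf("  fixed %d | lost %d | segregating %d  (fixation frequency %.3f)\n",
              x$fixed, x$lost, x$segregating, x$fixation_frequency))
  invisible(x)
}
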