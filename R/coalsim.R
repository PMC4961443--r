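#' Deme size trajectory
#'
#' Backward-in-time exponential trajectory: at `t` generations before
#' present the deme holds `n0 * exp(r t)` haploid gene copies with
#' `r = ln(n1/n0) / t_lgm`, reaching `n1` at the LGM (`t_lgm` generations)
#' and staying constant at `n1` further back. A negative `r` therefore
#' means a population larger now than in the past.
#'
#' @param n0 present haploid deme size.
#' @param n1 deme size at `t_lgm`.
#' @param t_lgm generations between present and the LGM.
#' @param extinct_at generation of (backward) extinction, after which any
#'   surviving lineages transfer to the source deme; `NA` for never.
#' @return object of class `deme_trajectory`.
#' @export
deme_trajectory <- function(n0, n1, t_lgm = 1750, extinct_at = NA) {
  stopifnot(n0 > 0, n1 > 0, t_lgm > 0)
  structure(list(n0 = n0, n1 = n1, t_lgm = t_lgm,
                 r = log(n1 / n0) / t_lgm,
                 extinct_at = extinct_at),
            class = "deme_trajectory")
}

#' @rdname deme_trajectory
#' @param traj a `deme_trajectory`.
#' @param t generations before present (vectorized).
#' @export
deme_size <- function(traj, t) {
  ifelse(t >= traj$t_lgm, traj$n1, pmax(traj$n0 * exp(traj$r * t), 1))
}

#' Simulate a genealogy under the discrete-generation structured coalescent
#'
#' Backward simulation with BayeSSC-style semantics: each generation, every
#' lineage outside the source deme (deme 1) migrates there with probability
#' `migration`; demes past their extinction generation transfer any
#' survivors to the source; within each deme coalescence uses exact
#' Wright-Fisher parent sampling when `k(k-1)/(2N) > wf_threshold` (so
#' multiple mergers are possible when demes are small) and a Bernoulli
#' pairwise approximation otherwise. Multiple mergers are binarized as
#' chains of coincident nodes, so a genealogy of `n` tips always has `n-1`
#' internal nodes.
#'
#' @param trajectories list of [deme_trajectory()], one per deme (deme 1 is
#'   the source).
#' @param sample_sizes integer vector of sampled lineages per deme.
#' @param migration per-generation probability that a lineage moves to the
#'   source deme.
#' @param seed optional integer seed.
#' @param wf_threshold regime switch for exact parent sampling.
#' @param gen_cap error out if no MRCA by this many generations (guards
#'   `migration = 0` with multiple occupied demes).
#' @return object of class `genealogy`: `parent` (1-based, `NA` at root),
#'   `time` (generations), `deme`, `n_tips`, `tmrca`.
#' @export
simulate_genealogy <- function(trajectories, sample_sizes, migration,
                               seed = NULL, wf_threshold = 0.1,
                               gen_cap = 1e8) {
  if (inherits(trajectories, "deme_trajectory"))
    trajectories <- list(trajectories)
  stopifnot(length(trajectories) == length(sample_sizes))
  if (!is.null(seed)) set.seed(seed)
  t_lgm <- trajectories[[1L]]$t_lgm
  n0 <- vapply(trajectories, `[[`, 0, "n0")
  n1 <- vapply(trajectories, `[[`, 0, "n1")
  ext <- vapply(trajectories, function(x)
    if (is.na(x$extinct_at)) -1L else as.integer(x$extinct_at), 0L)
  res <- sim_genealogy_cpp(as.integer(sample_sizes), n0, n1, t_lgm,
                           migration, ext, wf_threshold, gen_cap)
  structure(c(res, list(tip_deme = res$deme[seq_len(res$n_tips)])),
            class = "genealogy")
}

#' Construct a genealogy by hand
#'
#' Mostly useful for fixed-topology tests: supply parent pointers and node
#' times directly (tips first, times non-decreasing toward the root).
#' @param parent 1-based parent index per node, `NA` at the root.
#' @param time node times in generations (tips at 0).
#' @param n_tips number of tips.
#' @param deme optional deme label per node (defaults to 1).
#' @return a `genealogy`.
#' @export
genealogy <- function(parent, time, n_tips, deme = NULL) {
  stopifnot(length(parent) == length(time), sum(is.na(parent)) == 1L)
  deme <- deme %||% rep(1L, length(parent))
  structure(list(parent = parent, time = time, deme = deme,
                 n_tips = as.integer(n_tips),
                 tmrca = max(time),
                 tip_deme = deme[seq_len(n_tips)]),
            class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("<genealogy> %d tips, TMRCA = %.1f generations\n",
              x$n_tips, x$tmrca))
  invisible(x)
}

#' Evolve finite-sites sequences along a genealogy
#'
#' Per-site rate multipliers are drawn once from `Gamma(alpha, alpha)`
#' (continuous rate heterogeneity), the ancestral sequence is drawn from the
#' model's base frequencies, and substitutions are placed along each branch
#' as a per-site continuous-time Markov process (uniformization), so
#' multiple hits at a site are possible. Tips are returned in sampling
#' order.
#'
#' @param gen a [genealogy()].
#' @param model a [mutation_model()].
#' @param seed optional seed.
#' @param sample_ids tip names (default `t1..tn`).
#' @param locus_name label for the returned alignment.
#' @return a [locus_alignment()] of the tip sequences.
#' @export
evolve_sequences <- function(gen, model, seed = NULL, sample_ids = NULL,
                             locus_name = model$model) {
  stopifnot(inherits(gen, "genealogy"), inherits(model, "mutation_model"))
  if (!is.null(seed)) set.seed(seed)
  rates <- draw_site_rates(model)
  sim <- sim_sequences_cpp(gen$parent, gen$time, gen$n_tips, rates,
                           model$Q, model$freqs)
  bases <- c("A", "C", "G", "T")
  mat <- matrix(bases[sim$root_seq], gen$n_tips, model$L, byrow = TRUE)
  if (length(sim$var_sites))
    mat[, sim$var_sites] <- bases[sim$tip_states]
  rownames(mat) <- sample_ids %||% paste0("t", seq_len(gen$n_tips))
  locus_alignment(mat, locus_name)
}

# pooled h and pi straight from the variable-site tip states; the fast path
# used inside replicate loops (identical values to collapsing the full
# alignment because invariant sites cannot split haplotypes)
rep_stats <- function(tip_states, n_tips, L) {
  if (is.null(dim(tip_states)) || ncol(tip_states) == 0L)
    return(c(h = 0, pi = 0))
  key <- do.call(paste, c(as.data.frame(tip_states), sep = ","))
  first <- !duplicated(key)
  idx <- match(key, key[first])
  counts <- tabulate(idx, nbins = sum(first))
  n <- n_tips
  p <- counts / n
  h <- n * (1 - sum(p^2)) / (n - 1)
  U <- tip_states[first, , drop = FALSE]
  d <- hamming_pairs_cpp(U)
  w <- outer(counts, counts)
  tot <- sum(d[upper.tri(d)] * w[upper.tri(w)])
  c(h = h, pi = tot / (n * (n - 1) / 2) / L)
}

#' Simulate the replicate distributions of diversity statistics
#'
#' For each replicate: simulate a genealogy under the scenario, evolve
#' sequences, and record pooled haplotype and nucleotide diversity across
#' all demes. Each replicate runs in its own seed stream derived from
#' `(seed, replicate)`, so any subset is reproducible.
#'
#' @param scenario a [build_scenario()] result (or anything accepted by it).
#' @param model a [mutation_model()].
#' @param sample_sizes lineages sampled per deme; default the study design
#'   ([study_sample_sizes()]).
#' @param n_reps number of replicates.
#' @param seed master seed.
#' @param ploidy_factor multiplies deme gene-copy counts (1 organellar,
#'   2 nuclear loci sampled one sequence per individual).
#' @param locus label stored with the distributions.
#' @return object of class `simulated_distribution`: numeric vectors `h`
#'   and `pi` of length `n_reps`, replicate seeds, and metadata.
#' @export
run_scenario_replicates <- function(scenario, model,
                                    sample_sizes = study_sample_sizes(),
                                    n_reps = 2000L, seed = 1L,
                                    ploidy_factor = 1, locus = model$model) {
  scenario <- build_scenario(scenario)
  stopifnot(n_reps >= 1)
  trajs <- scenario_trajectories(scenario, ploidy_factor = ploidy_factor)
  if (length(sample_sizes) != scenario$demes)
    stop("sample_sizes must have one entry per deme")
  h <- numeric(n_reps)
  pi <- numeric(n_reps)
  seeds <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    seeds[r] <- derive_seed(seed, paste0("rep", r))
    set.seed(seeds[r])
    gen <- simulate_genealogy(trajs, sample_sizes, scenario$migration)
    rates <- draw_site_rates(model)
    sim <- sim_sequences_cpp(gen$parent, gen$time, gen$n_tips, rates,
                             model$Q, model$freqs)
    st <- rep_stats(sim$tip_states, gen$n_tips, model$L)
    h[r] <- st[["h"]]
    pi[r] <- st[["pi"]]
  }
  structure(list(h = h, pi = pi, seeds = seeds,
                 scenario = scenario$name, locus = locus,
                 n_reps = as.integer(n_reps)),
            class = "simulated_distribution")
}

#' @export
print.simulated_distribution <- function(x, ...) {
  cat(sprintf("<simulated_distribution> %s / %s: %d replicates (mean h = %.3f, mean pi = %.5f)\n",
              x$scenario, x$locus, x$n_reps, mean(x$h), mean(x$pi)))
  invisible(x)
}
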