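#' Haplotype diversity (Nei's unbiased estimator)
#'
#' `h = n (1 - sum p_i^2) / (n - 1)` over haplotype frequencies `p_i`; the
#' probability that two sequences drawn without replacement carry different
#' haplotypes.
#'
#' @param x a `haplotype_set` (see [collapse_haplotypes()]) or an integer
#'   vector of haplotype counts.
#' @return haplotype diversity in `[0, 1]`.
#' @export
haplotype_diversity <- function(x) {
  counts <- if (inherits(x, "haplotype_set")) haplotype_counts(x) else x
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity undefined for n < 2")
  p <- counts / n
  n * (1 - sum(p^2)) / (n - 1)
}

#' Nucleotide diversity (mean pairwise difference per site)
#'
#' `pi = 2 sum_{i<j} d_ij / (n (n-1) L)` with pairwise deletion of sites
#' where either sequence carries `N`; coded indel characters count as one
#' difference and one site each. Per-pair differences are standardized by
#' the sites actually compared for that pair, then averaged.
#'
#' The standard deviation is Nei's approximation
#' `V(pi) = (n+1) pi / (3 (n-1) L) + 2 (n^2 + n + 3) pi^2 / (9 n (n-1))`,
#' which combines sampling and stochastic variance.
#'
#' @param x a [locus_alignment()] or a `haplotype_set`.
#' @return list with `pi`, `pi_sd`, `n`, `L`.
#' @export
nucleotide_diversity <- function(x) {
  hapset <- if (inherits(x, "locus_alignment")) collapse_haplotypes(x) else x
  stopifnot(inherits(hapset, "haplotype_set"))
  n <- hapset$n
  if (n < 2) stop("nucleotide diversity undefined for n < 2")
  if (hapset$L < 1) stop("no usable sites")
  hd <- hap_distances(hapset)
  counts <- haplotype_counts(hapset)
  k <- hapset$k
  tot <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j < i) next
      w <- if (i == j) counts[i] * (counts[i] - 1) / 2 else counts[i] * counts[j]
      if (w == 0 || hd$sites[i, j] == 0) next
      if (i != j) tot <- tot + w * hd$d[i, j] / hd$sites[i, j]
    }
  }
  pi <- tot / (n * (n - 1) / 2)
  L <- hapset$L
  v <- (n + 1) * pi / (3 * (n - 1) * L) +
    2 * (n^2 + n + 3) * pi^2 / (9 * n * (n - 1))
  list(pi = pi, pi_sd = sqrt(max(v, 0)), n = n, L = L)
}

# per-individual squared-distance matrix from a haplotype set (number of
# differences used as the squared Euclidean distance, Arlequin convention)
.indiv_d2 <- function(hapset) {
  hd <- hap_distances(hapset)
  hd$d[hapset$assignment, hapset$assignment, drop = FALSE]
}

.amova_components <- function(d2, pop) {
  N <- length(pop)
  P <- length(unique(pop))
  ssd_total <- sum(d2) / (2 * N)
  ssd_within <- 0
  sizes <- table(pop)
  for (p in names(sizes)) {
    idx <- which(pop == p)
    ssd_within <- ssd_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ssd_among <- ssd_total - ssd_within
  df_a <- P - 1
  df_w <- N - P
  sigma_w <- ssd_within / df_w
  n_prime <- (N - sum(sizes^2) / N) / df_a
  sigma_a <- (ssd_among / df_a - sigma_w) / n_prime
  phi <- sigma_a / (sigma_a + sigma_w)
  list(ssd_total = ssd_total, ssd_among = ssd_among, ssd_within = ssd_within,
       sigma_a = sigma_a, sigma_w = sigma_w, phi_st = phi)
}

#' AMOVA Phi-ST from haplotype distances
#'
#' Excoffier-style analysis of molecular variance on the matrix of pairwise
#' haplotype differences (coded indel characters included, one step each).
#' `Phi_ST = sigma2_a / (sigma2_a + sigma2_w)`; significance by permuting
#' individuals among populations. Populations represented by a single
#' individual are excluded. Negative estimates are reported as computed.
#'
#' @param hapset a `haplotype_set` built with a population map.
#' @param n_perm number of permutations for the p-value (default 1000).
#' @param seed integer seed for the permutations.
#' @return object of class `amova_result` with variance components,
#'   `phi_st` and `p_value`.
#' @export
amova_phist <- function(hapset, n_perm = 1000L, seed = NULL) {
  stopifnot(inherits(hapset, "haplotype_set"))
  if (is.null(hapset$populations))
    stop("haplotype set was built without a population map")
  pop <- hapset$populations
  keep <- pop %in% names(which(table(pop) >= 2))
  if (length(unique(pop[keep])) < 2)
    stop("need at least 2 populations with n >= 2")
  d2 <- .indiv_d2(hapset)[keep, keep, drop = FALSE]
  pop <- pop[keep]
  obs <- .amova_components(d2, pop)
  p_value <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    ge <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample(length(pop))
      if (.amova_components(d2[perm, perm], pop)$phi_st >= obs$phi_st)
        ge <- ge + 1L
    }
    p_value <- (ge + 1) / (n_perm + 1)
  }
  structure(c(obs, list(p_value = p_value, n_perm = n_perm,
                        populations = sort(unique(pop)),
                        n = length(pop))),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("AMOVA: Phi_ST = %.4f (sigma2 among = %.4f, within = %.4f)",
              x$phi_st, x$sigma_a, x$sigma_w))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.4g (%d perms)", x$p_value, x$n_perm))
  cat("\n")
  if (x$phi_st < 0) cat("note: negative Phi_ST reported as computed\n")
  invisible(x)
}

#' Pairwise Phi-ST matrix
#'
#' [amova_phist()] applied to every pair of eligible populations.
#'
#' @inheritParams amova_phist
#' @return list with symmetric matrices `phi_st` and `p_value`
#'   (zero/`NA` diagonals).
#' @export
pairwise_phist <- function(hapset, n_perm = 1000L, seed = NULL) {
  stopifnot(inherits(hapset, "haplotype_set"))
  pop <- hapset$populations
  if (is.null(pop)) stop("haplotype set was built without a population map")
  eligible <- names(which(table(pop) >= 2))
  if (length(eligible) < 2) stop("need at least 2 populations with n >= 2")
  m <- matrix(NA_real_, length(eligible), length(eligible),
              dimnames = list(eligible, eligible))
  pm <- m
  diag(m) <- 0
  d2_all <- .indiv_d2(hapset)
  for (i in seq_len(length(eligible) - 1L)) {
    for (j in (i + 1L):length(eligible)) {
      keep <- pop %in% eligible[c(i, j)]
      d2 <- d2_all[keep, keep, drop = FALSE]
      sub_pop <- pop[keep]
      obs <- .amova_components(d2, sub_pop)
      m[i, j] <- m[j, i] <- obs$phi_st
      if (n_perm > 0) {
        if (!is.null(seed)) set.seed(derive_seed(seed, paste(i, j)))
        ge <- 0L
        for (b in seq_len(n_perm)) {
          perm <- sample(length(sub_pop))
          if (.amova_components(d2[perm, perm], sub_pop)$phi_st >= obs$phi_st)
            ge <- ge + 1L
        }
        pm[i, j] <- pm[j, i] <- (ge + 1) / (n_perm + 1)
      }
    }
  }
  list(phi_st = m, p_value = pm)
}

# log unsigned Stirling numbers of the first kind, rows 0..n
# c(n, k) = c(n-1, k-1) + (n-1) c(n-1, k), computed in log space
log_stirling1 <- function(n) {
  ls <- matrix(-Inf, n + 1L, n + 1L)
  ls[1L, 1L] <- 0 # c(0,0) = 1
  if (n >= 1L) {
    for (m in seq_len(n)) {
      for (k in seq_len(m)) {
        a <- ls[m, k] # c(m-1, k-1)
        b <- if (k + 1L <= m) log(m - 1) + ls[m, k + 1L] else -Inf
        ls[m + 1L, k + 1L] <- logsumexp(c(a, b))
      }
    }
  }
  ls
}

#' Ewens sampling-formula distribution of the number of haplotypes
#'
#' `Pr(K = k | theta, n)` via unsigned Stirling numbers of the first kind in
#' log space: `Pr(K = k) = |S(n, k)| theta^k / (theta)_n`.
#'
#' @param n sample size.
#' @param theta scaled mutation parameter (per locus).
#' @return numeric vector of probabilities for `k = 1..n` (sums to 1).
#' @export
ewens_k_distribution <- function(n, theta) {
  stopifnot(n >= 1, theta > 0)
  ls <- log_stirling1(n)
  logp <- ls[n + 1L, 2L:(n + 1L)] + seq_len(n) * log(theta) -
    sum(log(theta + 0:(n - 1L)))
  p <- exp(logp - logsumexp(logp))
  p
}

#' Fu's FS neutrality statistic
#'
#' `S' = Pr(K >= k_obs | theta_pi, n)` under the Ewens sampling formula with
#' `theta_pi` the mean number of pairwise differences per locus, and
#' `FS = ln(S' / (1 - S'))`. Strongly negative values indicate an excess of
#' haplotypes, the signature of demographic expansion. An optional p-value
#' is obtained by simulating `K` under the Ewens model at `theta_pi`
#' (Chinese-restaurant seating) and recomputing FS; by the usual convention
#' a simulated `p < 0.02` is treated as significant at the 5% level.
#'
#' @param hapset a `haplotype_set`, or `NULL` when `n`, `k` and `theta` are
#'   given directly.
#' @param n,k,theta sample size, observed haplotype count and per-locus
#'   theta; derived from `hapset` when omitted.
#' @param n_sim number of Ewens simulations for the p-value (0 = skip).
#' @param seed seed for the simulation p-value.
#' @return object of class `neutrality_result` with `fs`, `s_prime`, `k`,
#'   `theta_pi` and optional `p_value`.
#' @export
fu_fs <- function(hapset = NULL, n = NULL, k = NULL, theta = NULL,
                  n_sim = 0L, seed = NULL) {
  if (!is.null(hapset)) {
    stopifnot(inherits(hapset, "haplotype_set"))
    n <- n %||% hapset$n
    k <- k %||% hapset$k
    if (is.null(theta)) {
      nd <- nucleotide_diversity(hapset)
      theta <- nd$pi * nd$L # mean pairwise differences per locus
    }
  }
  stopifnot(!is.null(n), !is.null(k), !is.null(theta))
  if (n < 2) stop("Fu's FS undefined for n < 2")
  if (k <= 1 || theta <= 0)
    stop("Fu's FS undefined for k = 1 or theta = 0")
  p <- ewens_k_distribution(n, theta)
  s_prime <- sum(p[k:n])
  s_lower <- sum(p[seq_len(k - 1L)])
  fs <- log(s_prime) - log(s_lower)
  p_value <- NA_real_
  if (n_sim > 0) {
    if (!is.null(seed)) set.seed(seed)
    le <- 0L
    for (b in seq_len(n_sim)) {
      ksim <- 1L + sum(runif(n - 1L) < theta / (theta + seq_len(n - 1L)))
      if (ksim == 1L || ksim == n) {
        fsim <- if (ksim == 1L) Inf else -Inf
      } else {
        sp <- sum(p[ksim:n])
        fsim <- log(sp) - log1p(-sp)
      }
      if (fsim <= fs) le <- le + 1L
    }
    p_value <- (le + 1) / (n_sim + 1)
  }
  structure(list(fs = fs, s_prime = s_prime, k = k, n = n, theta_pi = theta,
                 p_value = p_value, n_sim = n_sim),
            class = "neutrality_result")
}

#' @export
print.neutrality_result <- function(x, ...) {
  cat(sprintf("Fu's FS = %.4f (k = %d, n = %d, theta_pi = %.4g)",
              x$fs, x$k, x$n, x$theta_pi))
  if (!is.na(x$p_value)) cat(sprintf(", simulated p = %.4g", x$p_value))
  cat("\n")
  invisible(x)
}

#' Slatkin-linearized fixation index
#' @param f fixation index (matrix or vector), `F < 1`.
#' @return `F / (1 - F)`.
#' @export
linearize_fst <- function(f) f / (1 - f)

# all permutations of 1..n (used for exhaustive Mantel enumeration)
.all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in .all_perms(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation between the lower-triangle entries, with significance
#' from permuting the rows/columns of the first matrix. `n_perm = "exact"`
#' enumerates all `n!` label permutations (the observed labelling included),
#' in which case the p-value is the exact fraction of permutations with
#' `r >= r_obs`.
#'
#' @param x,y square matrices with matching dimnames (or unlabelled and
#'   conformable). Cells where `exclude` is `TRUE` are dropped pairwise.
#' @param n_perm number of random permutations (default 10000) or
#'   `"exact"`.
#' @param seed seed for random permutations.
#' @param exclude optional logical matrix of cells to drop.
#' @return object of class `mantel_result` with `r`, `r2`, `p_value`,
#'   `n_permutations`.
#' @export
mantel_test <- function(x, y, n_perm = 10000L, seed = NULL, exclude = NULL) {
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)))
  n <- nrow(x)
  if (!is.null(dimnames(x)) && !is.null(dimnames(y)) &&
      !identical(rownames(x), rownames(y)))
    y <- y[rownames(x), rownames(x)]
  lower <- lower.tri(x)
  use <- lower
  if (!is.null(exclude)) use <- use & !(exclude | t(exclude))
  yv <- y[use]
  if (sd(yv) == 0 || sd(x[use]) == 0)
    stop("Mantel correlation undefined: constant matrix")
  corr <- function(xm) {
    xv <- xm[use]
    if (sd(xv) == 0) return(NA_real_)
    stats::cor(xv, yv)
  }
  r_obs <- corr(x)
  if (identical(n_perm, "exact")) {
    perms <- .all_perms(n)
    rs <- vapply(perms, function(p) corr(x[p, p]), numeric(1))
    p_value <- mean(rs >= r_obs - 1e-12, na.rm = TRUE)
    n_used <- length(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    ge <- 0L
    for (b in seq_len(n_perm)) {
      p <- sample(n)
      rp <- corr(x[p, p])
      if (!is.na(rp) && rp >= r_obs - 1e-12) ge <- ge + 1L
    }
    p_value <- (ge + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(r = r_obs, r2 = r_obs^2, p_value = p_value,
                 n_permutations = n_used),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f (r2 = %.4f), p = %.4g (%d permutations)\n",
              x$r, x$r2, x$p_value, x$n_permutations))
  invisible(x)
}

#' Isolation-by-distance Mantel test on log geographic distance
#'
#' Correlates a linearized fixation-index matrix (`F/(1-F)`, see
#' [linearize_fst()]) with the log10 great-circle distance between
#' population centroids (haversine, sphere radius 6371 km). Population
#' pairs at zero distance are excluded with a warning.
#'
#' @param fst_matrix square linearized-FST matrix with population dimnames.
#' @param popmap population map; centroids are the mean lat/lon per
#'   population.
#' @inheritParams mantel_test
#' @return a `mantel_result`.
#' @export
mantel_log_distance <- function(fst_matrix, popmap, n_perm = 10000L,
                                seed = NULL) {
  popmap <- validate_popmap(popmap)
  pops <- rownames(fst_matrix)
  stopifnot(!is.null(pops), identical(pops, colnames(fst_matrix)))
  cen <- do.call(rbind, lapply(pops, function(p) {
    sub <- popmap[popmap$population == p, , drop = FALSE]
    if (nrow(sub) == 0L) stop("population absent from map: ", p)
    c(mean(sub$lon), mean(sub$lat))
  }))
  gd <- matrix(0, length(pops), length(pops), dimnames = dimnames(fst_matrix))
  for (i in seq_len(length(pops) - 1L))
    for (j in (i + 1L):length(pops))
      gd[i, j] <- gd[j, i] <-
        geosphere::distHaversine(cen[i, ], cen[j, ], r = 6371000) / 1000
  zero <- gd == 0
  diag(zero) <- FALSE
  if (any(zero[lower.tri(zero)]))
    warning("population pairs at zero geographic distance excluded")
  logd <- gd
  logd[!zero] <- log10(pmax(gd[!zero], .Machine$double.eps))
  mantel_test(fst_matrix, logd, n_perm = n_perm, seed = seed,
              exclude = zero)
}

#' Effective population size from the mutation parameter
#'
#' `Ne = theta / (ploidy_factor * mu)` with `ploidy_factor` 2 for haploid
#' (organellar) and 4 for diploid nuclear loci.
#'
#' @param theta mutation parameter (per site).
#' @param mu per-site per-generation mutation rate (> 0).
#' @param ploidy_factor 2 or 4.
#' @return effective population size.
#' @export
ne_from_theta <- function(theta, mu, ploidy_factor = 2) {
  if (any(mu <= 0)) stop("mutation rate must be positive")
  if (!all(ploidy_factor %in% c(2, 4)))
    stop("ploidy_factor must be 2 (haploid) or 4 (diploid)")
  theta / (ploidy_factor * mu)
}

#' Per-population and overall diversity table
#'
#' One row per population (plus an overall row): sample size, haplotype
#' count `k`, haplotype diversity `h`, nucleotide diversity `pi` and its
#' standard deviation. Populations with a single sample get `NA` diversity.
#'
#' @param aln a [locus_alignment()].
#' @param popmap population map covering all samples.
#' @return data.frame.
#' @export
population_diversity <- function(aln, popmap) {
  popmap <- validate_popmap(popmap)
  idx <- match(aln$sample_ids, popmap$sample_id)
  if (anyNA(idx)) stop("samples missing from population map")
  pops <- popmap$population[idx]
  one <- function(ids, label) {
    sub <- locus_alignment(aln$seqs[ids, , drop = FALSE], aln$locus_name,
                           aln$usable_mask, aln$indels,
                           aln$indel_states[ids, , drop = FALSE])
    hs <- collapse_haplotypes(sub)
    if (hs$n >= 2) {
      nd <- nucleotide_diversity(hs)
      data.frame(population = label, n = hs$n, k = hs$k,
                 h = haplotype_diversity(hs), pi = nd$pi, pi_sd = nd$pi_sd,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(population = label, n = hs$n, k = hs$k,
                 h = NA_real_, pi = NA_real_, pi_sd = NA_real_,
                 stringsAsFactors = FALSE)
    }
  }
  rows <- lapply(sort(unique(pops)), function(p)
    one(aln$sample_ids[pops == p], p))
  rows[[length(rows) + 1L]] <- one(aln$sample_ids, "Overall")
  do.call(rbind, rows)
}
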