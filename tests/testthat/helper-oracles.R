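# Independent oracles used across the suite. These deliberately take
# different computational routes than the package implementation.

# continuous-time Kingman coalescent TMRCA for a single constant-size deme:
# sum of Exp(k(k-1)/(2N)) waiting times
kingman_tmrca_ct <- function(n, N, reps) {
  vapply(seq_len(reps), function(i) {
    sum(stats::rexp(n - 1, rate = choose(seq(n, 2), 2) / N))
  }, numeric(1))
}

# distribution of the number of distinct haplotypes under the Ewens sampling
# formula via sequential Chinese-restaurant seating (dynamic programming):
# customer i+1 opens a new table with probability theta / (theta + i)
crp_k_distribution <- function(n, theta) {
  probs <- 1 # P(K = 1) after the first customer
  for (i in seq_len(n - 1)) {
    p_new <- theta / (theta + i)
    probs <- c(probs * (1 - p_new), 0) + c(0, probs * p_new)
  }
  probs
}

# brute-force haplotype grouping by pairwise identity over given columns
brute_force_groups <- function(mat) {
  n <- nrow(mat)
  grp <- integer(n)
  next_grp <- 0L
  for (i in seq_len(n)) {
    if (grp[i] > 0L) next
    next_grp <- next_grp + 1L
    grp[i] <- next_grp
    if (i < n) for (j in (i + 1L):n)
      if (grp[j] == 0L && all(mat[i, ] == mat[j, ])) grp[j] <- next_grp
  }
  grp
}

# all permutations of 1..n (recursive, independent of the package internals)
perms_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# classical-ANOVA AMOVA oracle: haplotype differences on binary (0/1 per
# site) sequences equal squared Euclidean distances of the site indicator
# coordinates, so variance components follow from per-coordinate aov() sums
# of squares and the expected-mean-squares identities
amova_oracle <- function(coord, pop) {
  pop <- factor(pop)
  N <- nrow(coord)
  P <- nlevels(pop)
  ss_among <- ss_within <- 0
  for (j in seq_len(ncol(coord))) {
    fit <- stats::aov(coord[, j] ~ pop)
    ss <- summary(fit)[[1]][["Sum Sq"]]
    ss_among <- ss_among + ss[1]
    ss_within <- ss_within + ss[2]
  }
  sizes <- table(pop)
  sigma_w <- ss_within / (N - P)
  n_prime <- (N - sum(sizes^2) / N) / (P - 1)
  sigma_a <- (ss_among / (P - 1) - sigma_w) / n_prime
  list(sigma_a = sigma_a, sigma_w = sigma_w,
       phi_st = sigma_a / (sigma_a + sigma_w))
}

# nested-in-time two-way ANOVA oracle via aov() on one cell's response
anova_cell_oracle <- function(y_eat) {
  d <- dim(y_eat)
  df <- expand.grid(enm = factor(seq_len(d[1])), aogcm = factor(seq_len(d[2])),
                    time = factor(seq_len(d[3])))
  df$y <- as.vector(y_eat)
  ss <- summary(stats::aov(y ~ time / (enm * aogcm), data = df))[[1]][["Sum Sq"]]
  names(ss) <- c("time", "enm", "aogcm", "interaction")
  ss / sum(ss)
}

# small helper to build alignments from strings
make_aln <- function(strings, ids = NULL, locus = "toy") {
  mat <- do.call(rbind, strsplit(toupper(strings), ""))
  rownames(mat) <- ids %||% paste0("s", seq_along(strings))
  locus_alignment(mat, locus)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
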