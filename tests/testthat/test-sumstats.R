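test_that("haplotype diversity follows Nei's unbiased formula", {
  expect_equal(haplotype_diversity(c(1, 1)), 1.0)
  expect_equal(haplotype_diversity(c(4)), 0)
  expect_equal(haplotype_diversity(c(2, 1, 1)), (4 / 3) * (1 - 0.375))
  # invariant to permutation / relabeling of haplotypes
  expect_equal(haplotype_diversity(c(1, 2, 1)), haplotype_diversity(c(1, 1, 2)))
  expect_error(haplotype_diversity(c(1)), "n < 2")
})

test_that("nucleotide diversity equals the brute-force pairwise mean", {
  expect_equal(nucleotide_diversity(make_aln(rep("ACGTACGTAC", 3)))$pi, 0)
  expect_equal(nucleotide_diversity(make_aln(c("ACGTACGTAC", "ACGTACGTAT")))$pi,
               0.1)

  set.seed(42)
  mat <- matrix(sample(c("A", "C", "G", "T"), 4 * 100, replace = TRUE,
                       prob = c(0.7, 0.1, 0.1, 0.1)), 4, 100)
  rownames(mat) <- paste0("s", 1:4)
  aln <- locus_alignment(mat, "rand")
  got <- nucleotide_diversity(aln)$pi
  # brute force over all 6 pairs
  tot <- 0
  for (i in 1:3) for (j in (i + 1):4)
    tot <- tot + mean(mat[i, ] != mat[j, ])
  expect_equal(got, tot / 6)
})

test_that("nucleotide diversity drops N sites pairwise", {
  # pair (1,2): 1 difference over 9 comparable sites
  aln <- make_aln(c("ACGTACGTAN", "ACGTACGTTT"))
  expect_equal(nucleotide_diversity(aln)$pi, 1 / 9)
})

test_that("AMOVA Phi_ST is 1 under fixation, ~0 under identical composition", {
  pm <- data.frame(sample_id = paste0("s", 1:8),
                   population = rep(c("A", "B"), each = 4),
                   lat = rep(c(-10, -15), each = 4),
                   lon = rep(c(-45, -50), each = 4))
  fixed <- make_aln(c(rep("AAAA", 4), rep("AAAT", 4)), ids = pm$sample_id)
  res <- amova_phist(collapse_haplotypes(fixed, pm), n_perm = 0)
  expect_equal(res$phi_st, 1)

  mixed <- make_aln(rep(c("AAAA", "AAAT"), 4), ids = pm$sample_id)
  res2 <- amova_phist(collapse_haplotypes(mixed, pm), n_perm = 0)
  expect_lt(res2$phi_st, 0.05) # negative estimates allowed
})

test_that("AMOVA variance components match the classical-ANOVA oracle", {
  # binary sequences: haplotype differences are squared Euclidean distances
  # of the 0/1 site coordinates, so aov() per coordinate is an independent
  # route to the same decomposition (3 populations, 12 samples, unequal n)
  set.seed(5)
  coord <- matrix(rbinom(12 * 5, 1, 0.4), 12, 5)
  coord[1:4, 1:2] <- 1 # give population A some structure
  pop <- rep(c("A", "B", "C"), c(4, 5, 3))
  mat <- matrix(c("A", "T")[coord + 1], 12, 5)
  rownames(mat) <- paste0("s", 1:12)
  pm <- data.frame(sample_id = rownames(mat), population = pop,
                   lat = 0, lon = 0)
  res <- amova_phist(collapse_haplotypes(locus_alignment(mat, "toy"), pm),
                     n_perm = 200, seed = 9)
  oracle <- amova_oracle(coord, pop)
  expect_equal(res$phi_st, oracle$phi_st, tolerance = 1e-12)
  expect_equal(res$sigma_a, oracle$sigma_a, tolerance = 1e-12)
  expect_equal(res$sigma_w, oracle$sigma_w, tolerance = 1e-12)
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)
})

test_that("pairwise Phi_ST is symmetric and consistent with the two-pop AMOVA", {
  set.seed(11)
  mat <- matrix(sample(c("A", "T"), 15 * 6, replace = TRUE), 15, 6)
  rownames(mat) <- paste0("s", 1:15)
  pop <- rep(c("A", "B", "C"), each = 5)
  pm <- data.frame(sample_id = rownames(mat), population = pop,
                   lat = 0, lon = 0)
  hs <- collapse_haplotypes(locus_alignment(mat, "toy"), pm)
  pw <- pairwise_phist(hs, n_perm = 0)
  expect_equal(pw$phi_st, t(pw$phi_st))
  expect_equal(unname(diag(pw$phi_st)), rep(0, 3))
  # two-population subset equals the matrix entry
  keep <- pop %in% c("A", "B")
  hs_ab <- collapse_haplotypes(
    locus_alignment(mat[keep, , drop = FALSE], "toy"), pm[keep, ])
  expect_equal(amova_phist(hs_ab, n_perm = 0)$phi_st, pw$phi_st["A", "B"])
})

test_that("Fu's FS matches its closed forms and the seating-process oracle", {
  # n = 2, theta = 1: Pr(K = 2) = theta/(1+theta) = 1/2, FS = 0
  expect_equal(fu_fs(n = 2, k = 2, theta = 1)$fs, 0)
  # n = 5, k = 3, theta = 1: Pr(K >= 3) = 46/120
  expect_equal(fu_fs(n = 5, k = 3, theta = 1)$fs, log(46 / 74))

  for (n in 2:8) {
    for (theta in c(0.5, 1, 5)) {
      oracle <- crp_k_distribution(n, theta)
      expect_equal(ewens_k_distribution(n, theta), oracle, tolerance = 1e-12)
      for (k in 2:n) {
        if (k == 1 || sum(oracle[k:n]) %in% c(0, 1)) next
        expect_equal(fu_fs(n = n, k = k, theta = theta)$fs,
                     log(sum(oracle[k:n])) - log(sum(oracle[1:(k - 1)])),
                     tolerance = 1e-10)
      }
    }
  }

  # FS decreases as the observed haplotype count grows at fixed theta
  fs_vals <- vapply(2:7, function(k) fu_fs(n = 8, k = k, theta = 2)$fs,
                    numeric(1))
  expect_true(all(diff(fs_vals) < 0))

  expect_error(fu_fs(n = 5, k = 1, theta = 1), "undefined")
  expect_error(fu_fs(n = 5, k = 3, theta = 0), "undefined")
})

test_that("Fu's FS simulation p-value is reproducible and in range", {
  r <- fu_fs(n = 20, k = 12, theta = 3, n_sim = 300, seed = 4)
  r2 <- fu_fs(n = 20, k = 12, theta = 3, n_sim = 300, seed = 4)
  expect_identical(r$p_value, r2$p_value)
  expect_gt(r$p_value, 0)
  expect_lte(r$p_value, 1)
})

test_that("Mantel test recovers perfect correlation and rejects degenerate input", {
  m <- matrix(runif(16), 4, 4)
  m <- m + t(m); diag(m) <- 0
  expect_equal(mantel_test(m, m, n_perm = 99, seed = 1)$r, 1)
  const <- matrix(1, 4, 4); diag(const) <- 0
  expect_error(mantel_test(const, m), "constant")
})

test_that("exact Mantel p equals exhaustive enumeration (n = 4)", {
  set.seed(3)
  x <- matrix(runif(16), 4, 4); x <- x + t(x); diag(x) <- 0
  y <- matrix(runif(16), 4, 4); y <- y + t(y); diag(y) <- 0
  got <- mantel_test(x, y, n_perm = "exact")
  P <- perms_of(4)
  lower <- lower.tri(x)
  r_obs <- cor(x[lower], y[lower])
  rs <- apply(P, 1, function(p) cor(x[p, p][lower], y[lower]))
  expect_equal(got$r, r_obs)
  expect_equal(got$p_value, mean(rs >= r_obs - 1e-12))
  expect_identical(got$n_permutations, 24L)
})

test_that("Mantel r agrees with vegan's statistic", {
  skip_if_not_installed("vegan")
  set.seed(8)
  x <- as.matrix(dist(matrix(rnorm(14), 7, 2)))
  y <- as.matrix(dist(matrix(rnorm(14), 7, 2)))
  got <- mantel_test(x, y, n_perm = 99, seed = 2)
  ref <- vegan::mantel(x, y, permutations = 99)
  expect_equal(got$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("log-distance Mantel excludes coincident populations with a warning", {
  pm <- data.frame(sample_id = paste0("s", 1:4),
                   population = c("A", "B", "C", "D"),
                   lat = c(-10, -10, -12, -14), lon = c(-45, -45, -47, -49))
  f <- matrix(runif(16, 0.1, 0.6), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  f <- (f + t(f)) / 2; diag(f) <- 0
  expect_warning(res <- mantel_log_distance(linearize_fst(f), pm,
                                            n_perm = 99, seed = 1),
                 "zero geographic distance")
  expect_true(res$r >= -1 && res$r <= 1)
})

test_that("theta -> Ne conversion is linear with the documented ploidy factors", {
  mu <- 3.12e-7
  expect_equal(ne_from_theta(0, mu, 2), 0)
  expect_equal(ne_from_theta(2 * 0.001, mu, 2), 2 * ne_from_theta(0.001, mu, 2))
  expect_equal(ne_from_theta(0.001, mu, 4), ne_from_theta(0.001, mu, 2) / 2)
  expect_error(ne_from_theta(0.001, 0, 2), "positive")
  expect_error(ne_from_theta(0.001, mu, 3), "ploidy_factor")
})

test_that("per-population diversity table mirrors the per-locus summaries", {
  aln <- make_aln(c("AAAA", "AAAT", "AAAA", "TTTT", "TTTA"),
                  ids = paste0("s", 1:5))
  pm <- data.frame(sample_id = paste0("s", 1:5),
                   population = c("A", "A", "A", "B", "B"),
                   lat = 0, lon = 0)
  tab <- population_diversity(aln, pm)
  expect_identical(tab$population, c("A", "B", "Overall"))
  expect_equal(tab$n, c(3, 2, 5))
  expect_equal(tab$k, c(2, 2, 4))
  expect_equal(tab$h[2], 1.0)
})
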