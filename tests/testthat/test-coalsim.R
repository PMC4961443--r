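test_that("mutation models respect their class constraints and scaling", {
  m <- mutation_model("GTR", mu = 1e-6, L = 100,
                      exchangeabilities = c(1, 4, 2, 3, 5, 6),
                      freqs = c(0.4, 0.3, 0.2, 0.1))
  expect_equal(rowSums(m$Q), rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(-sum(m$freqs * diag(m$Q)), 1, tolerance = 1e-12)

  tvm <- mutation_model("TVM", mu = 1e-6, L = 10,
                        exchangeabilities = c(1, 4, 2, 3, 6, 5))
  expect_equal(tvm$exchangeabilities[["AG"]], tvm$exchangeabilities[["CT"]])
  tim2 <- mutation_model("TIM2", mu = 1e-6, L = 10,
                         exchangeabilities = c(1, 4, 2, 3, 6, 5))
  expect_equal(tim2$exchangeabilities[["AC"]], tim2$exchangeabilities[["AT"]])
  expect_equal(tim2$exchangeabilities[["CG"]], tim2$exchangeabilities[["GT"]])

  jc <- mutation_model("JC", mu = 1e-6, L = 10)
  expect_equal(unname(jc$Q[1, -1]), rep(1 / 3, 3))
  expect_error(mutation_model("JC", mu = 1e-6, L = 10, freqs = c(1, 1, 1, 1)),
               "summing to 1")
  expect_error(mutation_model("JC", mu = 1e-6, L = 10, gamma_shape = -1),
               "positive")
})

test_that("deme trajectories interpolate exponentially between N0 and N1", {
  tr <- deme_trajectory(1000, 100, 1750)
  expect_equal(deme_size(tr, 0), 1000)
  expect_equal(deme_size(tr, 1750), 100)
  expect_equal(deme_size(tr, 5000), 100)
  expect_equal(deme_size(tr, 875), 1000 * exp(tr$r * 875))
  expect_equal(tr$r, log(0.1) / 1750)
})

test_that("genealogies satisfy the structural invariants", {
  tr <- lapply(1:4, function(d)
    deme_trajectory(500, 200, 1750, extinct_at = if (d > 1) 1750 else NA))
  g <- simulate_genealogy(tr, c(5, 4, 3, 2), migration = 0.01, seed = 21)
  n <- g$n_tips
  expect_identical(n, 14L)
  expect_identical(length(g$parent), 2L * n - 1L)
  expect_identical(sum(is.na(g$parent)), 1L) # single root: n-1 coalescences
  expect_equal(g$time[seq_len(n)], rep(0, n))
  # times non-decreasing from child to parent
  kid <- which(!is.na(g$parent))
  expect_true(all(g$time[g$parent[kid]] >= g$time[kid]))
  # tip deme labels follow the sample configuration
  expect_identical(g$tip_deme, rep(1:4, c(5, 4, 3, 2)))
  # with migration + extinction at the LGM every post-LGM node is in deme 1
  expect_true(all(g$deme[g$time > 1750] == 1L))
})

test_that("simulation is reproducible from its seed", {
  tr <- deme_trajectory(300, 300, 1750)
  g1 <- simulate_genealogy(list(tr), 8, 0, seed = 5)
  g2 <- simulate_genealogy(list(tr), 8, 0, seed = 5)
  expect_identical(g1$parent, g2$parent)
  expect_identical(g1$time, g2$time)
  m <- mutation_model("JC", mu = 1e-3, L = 50)
  a1 <- evolve_sequences(g1, m, seed = 9)
  a2 <- evolve_sequences(g2, m, seed = 9)
  expect_identical(a1$seqs, a2$seqs)
})

test_that("no-coalescence configurations hit the generation cap", {
  tr <- lapply(1:2, function(d) deme_trajectory(100, 100, 10))
  expect_error(simulate_genealogy(tr, c(1, 1), migration = 0, gen_cap = 500),
               "generation cap")
})

test_that("single-deme TMRCA matches the Kingman expectation", {
  tr <- deme_trajectory(1000, 1000, 1750)
  set.seed(31)
  t2 <- replicate(800, simulate_genealogy(list(tr), 2, 0)$tmrca)
  expect_lt(abs(mean(t2) - 1000), 3 * sd(t2) / sqrt(length(t2)))
})

test_that("one-way migration follows per-generation Bernoulli trials", {
  # two lineages in demes 2 and 3, deme 1 of size 1: they coalesce in the
  # generation both have migrated, so TMRCA ~ max of two geometric(0.01)
  # variables with support {1, 2, ...}; E = 2/p - 1/(2p - p^2)
  p <- 0.01
  expected <- 2 / p - 1 / (2 * p - p^2)
  tr <- lapply(1:3, function(d) deme_trajectory(1, 1, 5000))
  set.seed(13)
  waits <- replicate(3000, simulate_genealogy(tr, c(0, 1, 1), migration = p)$tmrca)
  expect_lt(abs(mean(waits) - expected), 3 * sd(waits) / sqrt(length(waits)))
})

test_that("sequence evolution is exact under the JC closed form", {
  m0 <- mutation_model("JC", mu = 0, L = 30)
  g2 <- genealogy(parent = c(3L, 3L, NA), time = c(0, 0, 1000), n_tips = 2)
  aln0 <- evolve_sequences(g2, m0, seed = 1)
  expect_identical(aln0$seqs[1, ], aln0$seqs[2, ])
  expect_equal(nucleotide_diversity(aln0)$pi, 0)

  # mu*T = 0.005 per branch: expected difference fraction
  # p = 3/4 (1 - exp(-8 mu T / 3)) ~ 0.0099337
  mu <- 5e-6; T <- 1000
  m <- mutation_model("JC", mu = mu, L = 60000)
  g <- genealogy(parent = c(3L, 3L, NA), time = c(0, 0, T), n_tips = 2)
  aln <- evolve_sequences(g, m, seed = 2)
  p_hat <- mean(aln$seqs[1, ] != aln$seqs[2, ])
  p_exp <- 0.75 * (1 - exp(-8 * mu * T / 3))
  se <- sqrt(p_exp * (1 - p_exp) / m$L)
  expect_lt(abs(p_hat - p_exp), 4 * se)
})

test_that("large gamma shape converges to the uniform-rate distribution of pi", {
  tr <- deme_trajectory(400, 400, 1750)
  sim_pi <- function(model, seed) {
    set.seed(seed)
    replicate(250, {
      g <- simulate_genealogy(list(tr), 8, 0)
      nucleotide_diversity(evolve_sequences(g, model))$pi
    })
  }
  m_flat <- mutation_model("JC", mu = 2e-4, L = 300)
  m_big <- mutation_model("JC", mu = 2e-4, L = 300, gamma_shape = 1e6)
  ks <- suppressWarnings(stats::ks.test(sim_pi(m_flat, 101), sim_pi(m_big, 202)))
  expect_gt(ks$p.value, 0.01)
})

test_that("replicate distributions are seed-deterministic and sized correctly", {
  scn <- build_scenario("RETRACTION", demes = 3L)
  m <- mutation_model("JC", mu = 1e-5, L = 200)
  d1 <- run_scenario_replicates(scn, m, sample_sizes = c(4, 3, 3),
                                n_reps = 20, seed = 77)
  d2 <- run_scenario_replicates(scn, m, sample_sizes = c(4, 3, 3),
                                n_reps = 20, seed = 77)
  expect_identical(d1$h, d2$h)
  expect_identical(d1$pi, d2$pi)
  expect_identical(d1$n_reps, 20L)
  expect_true(all(d1$h >= 0 & d1$h <= 1))
  expect_true(all(d1$pi >= 0))

  # mu = 0 collapses both statistics to zero
  d0 <- run_scenario_replicates(scn, mutation_model("JC", mu = 0, L = 50),
                                sample_sizes = c(4, 3, 3), n_reps = 3,
                                seed = 1)
  expect_identical(d0$h, rep(0, 3))
  expect_identical(d0$pi, rep(0, 3))
})

test_that("the fast replicate statistics equal the full alignment route", {
  scn <- build_scenario("PPPH", demes = 3L)
  m <- mutation_model("TIM2", mu = 2e-5, L = 150, gamma_shape = 0.5)
  d <- run_scenario_replicates(scn, m, sample_sizes = c(5, 3, 2),
                               n_reps = 5, seed = 31)
  trajs <- scenario_trajectories(scn)
  for (r in 1:5) {
    set.seed(d$seeds[r])
    g <- simulate_genealogy(trajs, c(5, 3, 2), scn$migration)
    aln <- evolve_sequences(g, m)
    hs <- collapse_haplotypes(aln)
    expect_equal(haplotype_diversity(hs), d$h[r])
    expect_equal(nucleotide_diversity(hs)$pi, d$pi[r])
  }
})
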