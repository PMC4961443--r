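# coalscen

Simulation-based testing of demographic hypotheses in phylogeography.

Many plant and animal groups of the South American seasonally dry tropical
forests occur today as scattered, disjunct populations. Whether that pattern
is the relict of a once-continuous glacial-age forest (the "dry forest
refugia" idea, in its Pleistocene-arc and Amazonian-shift variants) or the
opposite — a glacial range and population *retraction* — can be judged from
present-day sequence data, because the competing histories predict different
levels of haplotype and nucleotide diversity. `coalscen` implements that
test as a reusable pipeline for multi-population, multi-locus sequence data:

* **Structured coalescent simulator** (Rcpp): discrete-generation backward
  simulation across 18 demes with exponentially changing deme sizes
  (`N(t) = N0 e^{rt}`, `r = ln(N1/N0)/t_LGM`), one-way migration to a source
  deme (0.01/generation), optional deme extinction at the LGM, and exact
  Wright-Fisher parent sampling (multiple mergers) when
  `k(k-1)/2N > 0.1`.
* **Finite-sites sequence evolution**: GTR-family models (JC, HKY, TVM,
  TIM2, GTR) with continuous gamma rate heterogeneity, exact multiple-hit
  handling by uniformization.
* **Summary statistics**: haplotype diversity
  `h = n(1 - Σp²)/(n-1)`, nucleotide diversity `π` (pairwise deletion),
  AMOVA `Φ_ST` with permutation tests, Fu's `F_S` via the Ewens sampling
  formula, Mantel tests of linearized `F/(1-F)` against log geographic
  distance, and `Ne = θ/(2μ)` conversions.
* **Model selection**: two-tailed simulation probabilities
  `P = min(1, 2·#{x > obs}/R)`, empirical log-likelihoods from the replicate
  histograms, `AIC = -2 lnL + 2K` (`K = 2`), ΔAIC and Akaike weights
  `w ∝ exp(-ΔAIC/2)`.
* **Niche-ensemble uncertainty**: TSS scoring and filtering (TSS < 0.5),
  TSS-weighted consensus maps, 10th-percentile presence thresholds, and
  per-cell hierarchical ANOVA partitioning variance across time, ENM and
  AOGCM components.
* **Synthetic-data generators** reproducing the full study design
  (18 populations / 235 samples; a 1,519-site chloroplast-like locus under
  TVM+G α = 0.017 and a 506-site ITS-like locus under TIM2+G α = 0.094;
  μ = 3.12e-7/site/generation), so the whole pipeline is testable without
  any external data.

The four encoded hypotheses differ in the deme size at the LGM and in
whether demes collapse into the source deme: PLAH (N1 = 10,000), "Both"
(N1 = 50,000), PPPH (N1 = 500, extinction) and Range Retraction (N1 = 100,
extinction), all with N0 = 1,000 and 1,750 generations to the LGM (21 ky at
12 y/generation).

## Worked example

Generate a synthetic study under the Range Retraction scenario, then ask
which of the four scenarios best explains its diversity:

```r
library(coalscen)

build_scenario("Retraction")
#> <scenario> RETRACTION: 18 demes, N0 = 1000 -> N1 = 100 at t = 1750 generations
#>   migration to source deme 0.01/generation; extinction of demes 2-18: on
#>   backward growth rate r = -0.00131576/generation; 2000 replicates; generation time 12 y

ds <- generate_dataset(synthetic_dataset_spec("RETRACTION", seed = 7))
hs <- collapse_haplotypes(ds$alignments$cpDNA, ds$popmap)
hs
#> <haplotype_set> cpDNA: k = 13 haplotypes among n = 235 samples (1519 usable sites)
haplotype_diversity(hs)        # 0.201
nucleotide_diversity(hs)$pi    # 0.00014
fu_fs(hs)
#> Fu's FS = -20.1182 (k = 13, n = 235, theta_pi = 0.2186)

# reference distributions: 4 scenarios x 2 loci, 500 replicates each
models <- list(cpDNA = mutation_model("TVM", mu = 3.12e-7, L = 1519, gamma_shape = 0.017),
               ITS   = mutation_model("TIM2", mu = 3.12e-7, L = 506, gamma_shape = 0.094))
ploidy <- c(cpDNA = 1, ITS = 2)
sims <- list()
for (locus in names(models))
  for (s in c("PLAH", "PPPH", "BOTH", "RETRACTION"))
    sims[[locus]][[s]] <- run_scenario_replicates(
      s, models[[locus]], n_reps = 500,
      seed = derive_seed(7, paste(s, locus)),
      ploidy_factor = ploidy[[locus]], locus = locus)

obs <- NULL
for (locus in names(ds$alignments)) {
  h <- collapse_haplotypes(ds$alignments[[locus]])
  obs <- rbind(obs, data.frame(locus = locus, statistic = c("h", "pi"),
                               value = c(haplotype_diversity(h),
                                         nucleotide_diversity(h)$pi)))
}
sel <- select_scenarios(obs, sims)
summary(sel)
#> Best scenario per statistic:
#>  locus statistic   scenario      aicw
#>  cpDNA         h RETRACTION 0.4861083
#>  cpDNA        pi RETRACTION 0.7254220
#>    ITS         h RETRACTION 0.7422372
#>    ITS        pi RETRACTION 0.8243170
#>
#> Combined evidence (summed lnL across statistics):
#>    scenario     lnL      AIC delta_aic   aicw plausible
#>        BOTH  5.8285  -7.6570   55.5212 0.0000     FALSE
#>        PLAH 11.1479 -18.2958   44.8824 0.0000     FALSE
#>        PPPH 29.5401 -55.0803    8.0979 0.0171     FALSE
#>  RETRACTION 33.5891 -63.1782    0.0000 0.9829     TRUE
#>
#> overall best scenario: RETRACTION
```

Each per-statistic block gives the two-tailed probability `P`, ΔAIC and
Akaike weight of every scenario; here the generating scenario (Retraction)
carries the maximal weight for all four statistics and 98% of the combined
evidence. `plot(sel)` overlays the observed value on the four replicate
histograms. `run_full_analysis()` wraps the same steps — alignment
post-processing, observed statistics, simulations, selection, and a
TSV/JSON/log report bundle — behind a single YAML-or-list configuration.

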