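---
title: "Testing demographic hypotheses by structured coalescent simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing demographic hypotheses by structured coalescent simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the method

Seasonally dry tropical forests in South America today form scattered,
disjunct patches. The "dry forest refugia" idea holds that this pattern is a
relict of a continuous forest belt at the Last Glacial Maximum (LGM, about
21 ka) that later fragmented. The alternative is the opposite dynamic: a
range and population *retraction* during the glacial, with post-glacial
expansion. The two histories leave different footprints in present-day
genetic diversity, so they can be confronted with sequence data through
simulation.

`coalscen` implements that confrontation as a reusable pipeline:

1. **Observed statistics.** Aligned chloroplast and nuclear sequences from a
   set of populations are post-processed (polymorphic mononucleotide repeats
   masked, gap intervals coded as single evolutionary events), collapsed to
   haplotypes, and summarized by haplotype diversity
   $h = \frac{n}{n-1}\,(1 - \sum_i p_i^2)$ and per-site nucleotide diversity
   $\pi$, plus AMOVA $\Phi_{ST}$, Fu's $F_S$ and Mantel tests as supporting
   descriptors.
2. **Simulated expectations.** Four named demographic scenarios are encoded
   as structured-coalescent models with 18 demes, and each is simulated
   (default 2,000 replicates per locus); every replicate yields a simulated
   $h$ and $\pi$, giving an empirical distribution of each statistic under
   each hypothesis.
3. **Model selection.** The observed statistic is scored against each
   distribution by a two-tailed simulation probability and an empirical
   log-likelihood; scenarios are ranked by AIC ($-2\ln L + 2K$, $K = 2$)
   and normalized Akaike weights.

## The demographic scenarios

All scenarios share: 18 demes; present haploid deme size $N_0 = 1000$; a
per-generation probability of 0.01 that any lineage outside deme 1 moves
(backward in time) to deme 1; and 1,750 generations between the present and
the LGM (21 ky at a 12-year generation time). Deme sizes change
exponentially between the present size $N_0$ and the LGM size $N_1$ at rate
$r = \ln(N_1/N_0)/1750$ per generation, and stay at $N_1$ further back in
time. The scenarios differ only in $N_1$ and in whether demes 2–18 go
extinct at the LGM (their surviving lineages then transfer to deme 1):

| scenario   | $N_1$  | extinction | reading                              |
|------------|--------|------------|--------------------------------------|
| PLAH       | 10,000 | no         | glacial expansion along the dry arc  |
| Both       | 50,000 | no         | arc expansion plus an Amazonian shift|
| PPPH       | 500    | yes        | range shift with smaller populations |
| Retraction | 100    | yes        | strong glacial contraction           |

A negative backward growth rate means the population is larger now than at
the LGM (PPPH, Retraction); a positive rate means it was larger at the LGM
(PLAH, Both). Since $N_1$ orders the scenarios, mean simulated diversity is
monotone along Retraction < PPPH < PLAH < Both — a property the test suite
verifies at 500 replicates per scenario.

## The simulator

`simulate_genealogy()` is a discrete-generation backward simulator
(serial-coalescent semantics in the style of SimCoal/BayeSSC), chosen over a
continuous-time formulation because migration is specified as a
*per-generation probability*. Within each generation: lineages outside the
source deme migrate there with probability $m$; demes past their extinction
generation hand surviving lineages to the source; each deme then undergoes
coalescence. Two regimes are used per deme and generation:

* when $k(k-1)/(2N) > 0.1$, exact Wright–Fisher parent sampling — each
  lineage draws a parent among $N$; lineages sharing a parent merge. This
  permits multiple mergers, which matter here because $N_1 = 100$ with up to
  235 lineages makes the Kingman approximation invalid;
* otherwise, a Bernoulli pairwise approximation (at most one merger per
  generation), accelerated by geometric waiting-time jumps once a single
  deme remains at constant size.

Multiple mergers are recorded as chains of binary nodes at the same
generation, so a genealogy of $n$ tips always carries exactly $n-1$
coalescences. The per-replicate correctness checks compare against analytic
expectations ($E[T_2] = N$; $E[T_{\mathrm{MRCA}}] = 2N(1 - 1/n)$) and
against an independent continuous-time Kingman sampler by a two-sample test.

`evolve_sequences()` places substitutions on the genealogy as a per-site
continuous-time Markov process via uniformization (events are Poisson with
rate $r_i\,q_{\max}$ per branch; each applies the jump-chain matrix
$I + Q/q_{\max}$), so multiple hits are handled exactly. Rate heterogeneity
is continuous: one $\mathrm{Gamma}(\alpha, \alpha)$ multiplier per site,
drawn once per replicate, matching serial-simulator behaviour rather than
discrete rate categories. The GTR-family models are parameterized by
exchangeabilities under the class constraints (TVM ties AG = CT; TIM2 ties
AC = AT and CG = GT), with the generator scaled to one expected substitution
per site per unit rate.

## Parameters that matter

* **Mutation rate** (`mu`): 3.12e-7 per site per generation by default —
  recovered from the constant ratio between the published $\theta$ and
  $N_e$ columns of the study's summary table ($\theta = 2\mu N_e$ for the
  organellar genome; equivalently 2.6e-8/site/year at 12-year generations).
* **Gamma shapes**: 0.0170 (chloroplast, TVM+G) and 0.0940 (ITS, TIM2+G),
  the shapes selected for the two partitions. Shapes this small concentrate
  nearly all substitution rate in a few sites.
* **Locus lengths**: 1,519 usable chloroplast sites and 506 usable ITS
  sites; "usable" counts masked nucleotide columns plus coded indel
  characters.
* **Ploidy factor**: nuclear loci are simulated with deme gene-copy counts
  multiplied by 2 while sampling one sequence per individual (the study
  found no heterozygotes, and recombination is neglected throughout).
* **Sample configuration**: the 18 published population sample sizes
  (235 total) by default.
* **Unprinted substitution-model details** (exchangeabilities, base
  frequencies) default to 1 within the class constraints and to uniform
  frequencies; both are overridable, and empirical frequencies of an input
  alignment are the natural override when data are available.

## Model selection: the empirical likelihood

The two-tailed probability is $P = \min(1,\; 2\,\#\{x > \mathrm{obs}\}/R)$:
twice the fraction of replicates above the observed value, ties counting as
"not higher" — a high $P$ means the model comfortably reproduces the
observation.

The likelihood of an observed value under a scenario is read off a histogram
of the replicates (Freedman–Diaconis bins by default; a fixed bin count or
explicit breaks can be supplied for exact reproducibility). Two readings of
"the product of the height of the distribution at the observed value by the
maximum height" are implemented:

* `product` (default): $\ln L = \ln(\hat f(\mathrm{obs}) \cdot \hat
  f_{\max})$ — the literal product;
* `ratio`: $\ln L = \ln(\hat f(\mathrm{obs}) / \hat f_{\max})$ — a
  normalized variant with $\ln L \le 0$.

The package defaults to the product reading on methodological grounds: the
ratio normalization cancels exactly the information that distinguishes a
sharply concentrated scenario distribution from a diffuse one, biasing
selection toward diffuse competitors (its expected value under the true
model is strictly negative and more so the more peaked the distribution).
The product reading preserves that information, and the end-to-end recovery
property exercised in the test suite — synthetic data generated under
Retraction and under Both must be assigned to their generating scenario by
maximal Akaike weight in at least 80% of 20 seeded repetitions at 500
replicates per scenario — holds under it. Zero-count bins and observations
outside the histogram support are floored at half a count,
$0.5/(R\,w)$, so every log-likelihood is finite.

Per statistic, scenarios are compared by $\mathrm{AIC} = -2\ln L + 2K$ with
$K = 2$ free parameters for every scenario, $\Delta$AIC, and weights
$w_i \propto e^{-\Delta_i/2}$ normalized to sum to one; models with
$\Delta\mathrm{AIC} < 2$ are flagged as equally plausible. For an overall
verdict the statistics (two loci × two statistics) are treated as
independent pieces of evidence: their log-likelihoods are summed into one
combined AIC comparison (the scenarios share the same $K$, which is not
summed). Summing the per-statistic normalized weights instead would flatten
strong evidence from any single statistic; the combined-likelihood rule is
the one the recovery tests exercise.

## The synthetic-data generator

`generate_dataset()` emulates the study design — 18 populations with the
published sample sizes, the two loci with their lengths, models, gamma
shapes and ploidy factors, and the default mutation rate — by running the
simulator once per locus under a named scenario and writing FASTA files, a
population map with synthetic coordinates (population centroids scattered
over a central-Brazil-like window), and a truth record (scenario, seeds,
TMRCAs) for recovery tests. Every artifact is byte-reproducible from the
spec and seed.

What it deliberately does **not** emulate: the spatial arrangement of the
real populations (demes are exchangeable labels; coordinates are synthetic
and so marked), selection, recombination, sequencing error, alignment
ambiguity, and the specific haplotype network of the real data. Passing the
recovery tests therefore shows that the pipeline can discriminate the four
hypotheses *under its own generative assumptions* at realistic sample sizes
and rates — not that the historical inference for any particular real
dataset is correct.

`generate_suitability_stack()` serves the niche-model module: it builds a
cells × 12 ENM × 5 AOGCM × 3 times suitability array as the logistic
transform of orthogonal effect components constructed to carry exact target
shares of the linear-scale sum of squares, plus per-model confusion counts
with known skill. Effects are kept small so the logistic link stays
near-linear and the ANOVA recovers the stated shares closely.

## Niche-ensemble uncertainty partitioning

The ENM post-processing follows the ensemble workflow: models with
TSS < 0.5 are dropped; the survivors are combined per cell as a TSS-weighted
mean; presence maps use the 10th-percentile lowest presence threshold
(linear interpolation between order statistics, `stats::quantile` type 7 —
the quantile convention is configurable since none is stated); and a
hierarchical ANOVA partitions each cell's 12 × 5 × 3 response into a time
component, ENM and AOGCM components nested in time (two-way factorial
within each period, summed across periods), their within-time interaction,
and a residual defined as the remainder (zero in this saturated design).
The partition is computed per cell with vectorized sums of squares — the
design is balanced, so the decomposition is exact — and a pooled,
SS-weighted summary is attached.

## Numerical choices and degenerate inputs

* Haplotype identity is exact string identity over usable columns plus
  indel characters (`N` is a state for identity, but is excluded pairwise
  in diversity and distance computations).
* "Mononucleotide microsatellite" is operationalized as a single-base run
  of length ≥ 5 (configurable) in any sequence, gaps collapsed; only
  polymorphic columns inside such runs are masked.
* Every gap interval is coded as one indel event by default
  (`min_indel_len = 1`), the conservative superset of "long indels";
  recoding is idempotent.
* Negative $\Phi_{ST}$ estimates are reported as computed, not truncated,
  preserving the estimator's distribution; permutation p-values use the
  add-one convention $(\#\{ \ge \mathrm{obs}\} + 1)/(B + 1)$.
* Fu's $F_S$ is computed from the Ewens sampling formula with unsigned
  Stirling numbers in log space; $\theta$ is the π-based per-locus mean
  pairwise difference. The optional p-value simulates the haplotype count
  by Chinese-restaurant seating; by the usual convention a simulated
  p < 0.02 is read as significant at the 5% level.
* Mantel tests correlate linearized $F/(1-F)$ with log10 great-circle
  distance (haversine, 6371 km radius); coincident populations are excluded
  pairwise with a warning; `n_perm = "exact"` enumerates all label
  permutations for small matrices.
* A constant replicate distribution is treated as a single unit-width bin;
  a constant per-cell ANOVA response yields flagged `NA` proportions.
* Degenerate simulator inputs (zero migration with multiple occupied demes
  and no extinction) terminate at a configurable generation cap with an
  explicit error.

## Reproducibility and problem sizes

A single top-level seed drives everything: stage and replicate seeds are
derived as deterministic hashes of `(seed, label)`, so any subset of a run
(one replicate, one scenario, one locus) can be regenerated in isolation.
The simulator is written in C++ (Rcpp) using R's RNG, so `set.seed()`
controls it fully.

The shipped test suite runs the distributional checks at 500 replicates per
scenario and 5,000 (mean) / 2,000 (distribution-comparison) replicates for
the coalescent calibration, and the recovery property at 20 seeded
repetitions against 500-replicate reference distributions; the reference
distributions are generated once per scenario — the repetitions vary the
observed synthetic dataset, which is the quantity under test. These sizes
keep the full suite around a minute on one CPU while leaving Monte Carlo
error far inside the asserted tolerances; all of them scale up by argument.

## Known limitations

* The simulator implements the one-way island model the scenarios specify —
  no general migration matrices, no recombination, no selection, no serial
  sampling.
* The empirical likelihood depends on the histogram rule; with 500–2,000
  replicates the Freedman–Diaconis choice is stable, but the absolute
  $\ln L$ values (unlike the rankings) should not be compared across
  binning rules.
* $\Phi_{ST}$ permutation tests permute individuals among populations
  globally; hierarchical (among-group) AMOVA designs are out of scope.
* The niche-model module post-processes suitability stacks; fitting the
  ENMs themselves, pseudo-absence design and climate layers are outside the
  package.
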