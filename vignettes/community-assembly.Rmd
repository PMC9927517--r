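---
title: "Methods: structure and assembly inference for phyllosphere ASV communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure and assembly inference for phyllosphere ASV communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phyllocom analyses amplicon sequence variant (ASV) count tables from paired
plant-microbiome surveys — its reference design is wild versus cultivated
rice leaves sampled at three sites with five replicate pairs — and asks two
families of questions: *who is there* (core membership, diversity,
differential abundance, co-occurrence structure) and *how the community got
there* (neutral immigration versus selection, dispersal limitation and
drift). This vignette documents the models, the tunable parameters, the
synthetic-data generators used for validation, and the numerical choices
behind each stage.

## Data model

All statistics operate on a `feature_table`: a taxon-by-sample matrix of
non-negative integer read counts with unique IDs and optional per-taxon
kingdom labels (`bacteria`/`fungi`). Because library sizes differ between
samples, every analysis is computed on per-sample relative abundances;
rarefaction is available (`rarefy_table()`) as a sensitivity check but is
not applied by default — proportions already remove depth effects for every
statistic used here, and discarding reads only adds noise. Samples carry
`site`, `genotype` and `replicate` factors that must align exactly with the
table's columns (`align_metadata()` enforces this and names any offender).

## Composition and diversity

Alpha diversity is the natural-log Shannon index on relative abundances.
Beta diversity is Bray-Curtis dissimilarity, again on proportions, so
entries lie in [0, 1]. Ordination is classical PCoA (eigendecomposition of
the double-centred −½D² matrix). Bray-Curtis is not Euclidean, so negative
eigenvalues occur; they are reported but excluded from the
proportion-explained denominator and no Cailliez correction is applied —
the axes are for display and their variance shares should not be inflated
by a constant added to every distance. PERMANOVA uses one factor at a time
with free permutation of sample labels (no strata), the behaviour of a
single-factor `adonis2` call; the per-factor R² therefore answers "how much
does this factor alone structure the distances", not a sequential
decomposition.

## Core membership and enrichment

Core taxa satisfy a strict AND of two published thresholds: prevalence 1
(present in every sample; a single absence disqualifies) and mean relative
abundance strictly above 0.1%. Both thresholds are exposed
(`prevalence_min`, `abundance_min`) and raising either can only shrink the
core set.

Differential abundance between the two genotypes is classified with the
published decision rule |log2 fold change| > 2 and Benjamini–Hochberg FDR
< 0.01. The fold change is the ratio of group mean relative abundances
after adding a pseudocount (half the smallest nonzero taxon mean, so the
shrinkage adapts to the table's scale); significance comes from a two-sided
Wilcoxon rank-sum test per taxon. This is a deliberate nonparametric
substitute for a negative-binomial GLM: the classification thresholds, not
the test statistic, carry the biological meaning, and the rank-sum test
needs no dispersion model on relative abundances. Exact parity with
count-model tools is a non-goal. Each group needs at least three samples
for the test to be defined; the fold change is oriented wild-over-cultivated
whenever a `wild` level is present.

## Co-occurrence networks

Networks are built per genotype on the merged two-kingdom table; the
inter-kingdom network is primary and the intra-kingdom networks are its
BB/FF edge-induced subgraphs. Before correlation screening, rare ASVs
(mean relative abundance < 0.01%) are removed to mitigate zero inflation.
All pairwise Spearman correlations are computed on relative abundances,
with two-sided p-values from the t approximation; taxa constant across
samples have undefined rank correlations and can never form edges. Edges
require |rho| > 0.6 AND BH-adjusted p < 0.01, both strict inequalities; the
BH family is all candidate pairs within one network build (the most
conservative defensible family; a `correction = "none"` flag exposes the
raw-p variant because the published wording is ambiguous about whether the
0.01 applies before or after adjustment). Isolated taxa are dropped.

Topology metrics (degree, local clustering, closeness, betweenness,
modularity) are computed on the unweighted, unsigned skeleton; signs are
retained only for the stability proportions (share of negative edges, with
greater modularity and more negative edges read as a more stable
community). Local clustering of a degree-<2 node is defined as 0.
Closeness is normalized within each connected component,
(n_comp − 1)/Σdistances. Community structure uses deterministic greedy
modularity maximization (`igraph::cluster_fast_greedy`) rather than
Louvain, trading a little modularity for exact reproducibility; the
algorithm name is recorded in every summary. Hub ranking is deterministic:
degree, then closeness, then lexicographic ID.

## Neutral community model

The Sloan model predicts a taxon's occurrence frequency from its
metacommunity relative abundance p: local relative abundances follow
Beta(Nm·p, Nm·(1−p)), so the predicted detection frequency at detection
limit d is 1 − BetaCDF(d; Nm·p, Nm·(1−p)). We take N as the mean per-sample
read depth and d = 1/N (the single-read detection limit, the convention of
the model's standard implementation lineage), estimate the metacommunity
abundance of each taxon by its mean relative abundance, and fit the single
free parameter Nm by bounded least squares — a golden-section search on
log Nm over [10⁻³, 10⁹], which is robust because the squared-error
objective is unimodal in log Nm in practice. R² is 1 − SSres/SStot of the
frequency fit; the migration rate is m = Nm/N. Each taxon is classified
against the 95% Wilson score interval around its predicted frequency at
n = number of samples (`above`/`within`/`below`); the deviating fraction is
above + below. A saturated table (every taxon everywhere) has zero
frequency variance: the fit returns R² = NA rather than failing. At least
10 samples are required — below that, occurrence frequencies are too coarse
for the fit to mean anything.

## Null-model assembly framework

Pairwise assembly processes are inferred in two steps. First the
phylogenetic signal: abundance-weighted beta mean-nearest-taxon distance
(βMNTD) between each sample pair, standardized against a null in which
taxon labels are shuffled across the tips of the whole tree. The z-score is
βNTI; |βNTI| > 2 indicates selection (> +2 heterogeneous, < −2
homogeneous). Abundance weighting matches the framework's standard use for
community data with read counts. All sample pairs share one sequence of
`n_null = 999` tip shuffles, keeping cost O(n_null · pairs) and making the
nulls identical across pairs — the per-pair z-scores remain valid because
each pair's observed value is compared to its own null distribution.
Because a z-score is scale-free, βNTI is invariant to uniform branch-length
rescaling. If a pair's null has zero variance (for example, two samples
that both contain every taxon, where βMNTD is 0 under any shuffle), its
βNTI is reported as missing and excluded, with a count, from the process
denominator.

Second, for pairs without selection signal, an abundance-based Raup-Crick
null on Bray-Curtis: each null community preserves its sample's observed
richness and read total, draws taxa without replacement with probability
proportional to occupancy across all samples, seeds each drawn taxon with
one read and fills the remainder multinomially in proportion to overall
relative abundance. This occupancy-proportional colonization /
abundance-proportional filling variant (recorded in the output metadata) is
the published default for sequence data. RC is the rescaled rank of the
observed dissimilarity in the null distribution, in [−1, 1]; RC > 0.95 is
dispersal limitation (acting with drift), RC < −0.95 homogenizing
dispersal, anything else undominated drift. The cuts ±2 and ±0.95 are
defaults, overridable. All statistics are computed within genotype, as in
the reference design; cross-genotype pairs are excluded.

Levins' niche breadth is B = 1/ΣP², with P the share of a taxon's total
reads per sample, ranging from 1 (one sample) to the sample count (even
spread); the community value Bcom is the mean over taxa.

## Synthetic-data generators

Every estimator is validated against generators with known ground truth,
under one explicit seed each (no global RNG state leaks; identical seeds
give byte-identical tables).

* **Metacommunity pool** — lognormal ranked-abundance distribution; the
  data give no basis for any particular pool shape, so the log-SD is
  exposed (`shape`, default 1.5, strong dominance typical of phyllosphere
  communities).
* **Neutral** — the exact generative inverse of the Sloan fit: per-sample
  Beta(Nm·p, Nm·(1−p)) relative abundances, then multinomial reads. This
  guarantees a parameter-recovery test: at 60 samples × 5,000 reads × 200
  taxa and Nm = 50, the fitted Nm lands within ±20% with R² > 0.7 in ≥90%
  of seeded replicates.
* **Selection** — a trait evolves by Brownian motion on a unit-depth
  pure-birth tree with rate 1, so root-to-tip trait SD is 1 and
  environmental optima are in trait-SD units; a Gaussian fitness filter
  exp(−(trait−env)²/(2·trait_sd²)) reweights the pool per sample. The
  default filter width 0.5 places the two-block scenario (env = ±2) firmly
  in the strong-selection regime, which is what a scenario named
  `heterogeneous_selection` should express.
* **Dispersal limitation** — restricted colonization with local drift: each
  site receives a pool subset (fraction `subsample_fraction`, drawn with
  probability proportional to pool abundance so that widespread taxa reach
  most sites, concentrating occupancy as in real data) and colonist
  abundances drift per site by a lognormal factor (`drift_sd = 3`). The
  drift scale was chosen so that site pools typically diverge by more than
  an order of magnitude in their dominant members: with only a handful of
  sites, weaker drift leaves site pairs whose dominants coincide by chance,
  and the scenario would sit between regimes instead of in the one it
  declares. A purely presence-based subsampling mechanism without drift
  cannot represent this regime at all — when every taxon is equally likely
  to colonize any site, occupancy is uniform and the Raup-Crick null draws
  communities distributionally identical to the observed ones, pinning RC
  near zero.
* **Planted network** — latent log-abundance factors shared by planted
  taxon pairs (sign-flipped for negative edges) with independent Gaussian
  noise (`noise_sd = 0.3`, giving latent correlations near 0.9), then
  multinomial reads. The network stage recovers ≥8/10 planted edges with
  ≤2 false edges (median over seeds) at the published thresholds.
* **Study-like tables** — designated core taxa receive fixed pool mass,
  designated taxa a known log2 enrichment per genotype, with lognormal
  site effects (SD 0.5) and per-sample noise (SD 0.3) creating the
  site/genotype structure that ordination and PERMANOVA recover.

What the generators deliberately do not emulate: read-level error and
chimeras, taxonomy mis-assignment, variable sequencing depth (uniform depth
is assumed; the survey data give no per-sample depth distribution, and
rarefaction is handled downstream), compositional correlation artefacts
beyond what multinomial sampling induces, and realistic phylogenies with
rate variation. Passing tests therefore demonstrate estimator correctness
and calibration under the stated models, not robustness to those real-data
complications.

## Problem sizes and numerical choices

Validation runs use desk-scale sizes chosen to keep the full suite fast
while leaving the statistics well-posed: tables of 100–350 taxa, 15–60
samples, 2,000–20,000 reads per sample, 999 permutations/null draws. Null
calibration of βNTI uses ≥200 sample pairs; the PERMANOVA type-I check uses
500 structureless datasets. Tolerances: exact closed forms at 1e-12 to
1e-8; graph metrics against brute-force recomputation at 1e-10; calibration
bands as stated above. Ties in hub ranking and the strictness of every
published threshold (>, not ≥) are covered by constructed fixtures. The
one-dimensional neutral fit cannot multi-start into local optima; the
greedy modularity and all null loops are seeded, so every reported number
is bit-reproducible from its configuration.

## Known limitations

The enrichment stage is not a count-model test and will rank very
low-abundance taxa differently from a negative-binomial GLM. Spearman
networks on relative abundances inherit compositional bias; SparCC-style
corrections are out of scope. The Raup-Crick null fixes richness, which
conflates richness differences with abundance structure for very uneven
pairs. βNTI assumes the tree's branch lengths are meaningful for trait
conservatism. The within-genotype grouping means the framework cannot
attribute processes to cross-genotype contrasts.
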