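---
title: "Phylogenetic null models for microbial community assembly: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic null models for microbial community assembly: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microassembly)
```

## The inference problem

Given a sample-by-OTU count table, a rooted phylogeny over the OTUs and a
mapping of samples to treatment groups, `microassembly` asks, for every pair
of samples: was the compositional difference between these two communities
produced by *deterministic* processes (environmental selection) or by
*stochastic* processes (dispersal and ecological drift)? The answer follows
the two-stage null-model framework widely used in microbial ecology.

**Stage 1 — phylogenetic turnover.** The between-community mean nearest
taxon distance for samples $k$ and $m$ is

$$\beta\mathrm{MNTD}(k,m) = \tfrac12 \Big[ \sum_{i \in k} f_{ik}\,
\min_{j \in m} d(i,j) \;+\; \sum_{j \in m} f_{jm}\, \min_{i \in k} d(i,j)
\Big],$$

where $f_{ik}$ is the relative abundance of taxon $i$ in sample $k$ and
$d$ the patristic distance. Its standardized effect size against a null
distribution is the beta nearest taxon index,

$$\beta\mathrm{NTI} = \frac{\beta\mathrm{MNTD}_\mathrm{obs} -
\overline{\beta\mathrm{MNTD}}_\mathrm{null}}{\mathrm{sd}
(\beta\mathrm{MNTD}_\mathrm{null})}.$$

The null model shuffles taxon labels across all tree tips (the
`taxa.labels` convention), which preserves every sample's richness and
abundance structure and randomizes only phylogenetic position. One shuffle
per draw is shared by both samples of a pair — a requirement, not an
optimization: identical communities must then produce a degenerate null
(every draw gives the same value), which the package flags as `NA` rather
than reporting a spurious 0. $|\beta\mathrm{NTI}| > 2$ is read as
deterministic assembly: $> 2$ more turnover than expected (variable
selection), $< -2$ less than expected (homogeneous selection).

**Stage 2 — Raup–Crick on the residual pairs.** Pairs with
$|\beta\mathrm{NTI}| \le 2$ are resolved by the Bray–Curtis-based
Raup–Crick metric. For each pair the observed Bray–Curtis dissimilarity is
ranked within a null distribution of dissimilarities between random
assemblages that preserve each sample's richness and total reads: taxa are
drawn without replacement with probability proportional to occupancy, each
drawn taxon receives one read, and the remaining reads are allotted with
probability proportional to metacommunity relative abundance.
$\mathrm{RC}_\mathrm{bray} = 2\,\big[(\#\{\mathrm{null} < \mathrm{obs}\} +
\tfrac12 \#\mathrm{ties})/n_\mathrm{null} - \tfrac12\big] \in [-1, 1]$;
ties (equality within $10^{-12}$) take half weight. Values above $0.95$
indicate dispersal limitation, below $-0.95$ homogenizing dispersal, and
the remainder drift. The five labels partition every classified pair, and
`summarize_processes()` reports the deterministic fraction (the two
selection labels) and its stochastic complement, overall and within groups.

Null communities are generated once per sample per draw and shared across
the pairs involving that sample; each pair's marginal null distribution is
identical to fully independent generation, at a twelfth of the cost for a
12-sample design.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_null` | 999 | null draws for ses.MNTD, βNTI and RC~bray~ (floor 99) |
| `n_perm` (Mantel) | 999 | permutations; $p = (1 + \#\{r_\mathrm{perm} \ge r\})/(1 + n)$ |
| `abundance_weighted` | `TRUE` | weight MNTD/βMNTD by relative abundance |
| βNTI thresholds | ±2 | deterministic vs stochastic turnover |
| RC~bray~ thresholds | ±0.95 | dispersal limitation / homogenizing dispersal vs drift |
| `dominance_threshold` | 0.005 | network: keep taxa with mean relative abundance > 0.5% |
| `rho_threshold`, `q_threshold` | 0.6, 0.01 | network edge gates on \|Spearman ρ\| and BH-adjusted merged p |
| `n_perm` (network) | 1000 | permutations per association metric |

The 999/0.5%/0.6/0.01 defaults are the conventional settings for this
analysis family; all are exposed as arguments. Tests and the bundled
acceptance script run the null models at 199 draws — the estimates of a
standardized effect size stabilize well below 999 draws, and the package's
own assertions are on coarse quantities (label fractions), not on
third-decimal βNTI values.

## Alpha diversity conventions

Shannon entropy defaults to log base 2. For OTU tables with thousands of
taxa the reported Shannon values of ~9–10 in this analysis tradition are
only attainable in bits ($\ln 4000 \approx 8.3$), so bits are the default
and the base is an argument. Simpson is reported as Gini–Simpson
($1 - \sum p_i^2$, larger = more diverse). Chao1 uses the bias-corrected
form $S_\mathrm{obs} + F_1(F_1-1)/(2(F_2+1))$, defined even without
doubletons; the classic form is behind a flag. ACE uses the standard
rare/abundant split at 10 reads with the rare-class coefficient of
variation floored at 0, falling back to Chao1 when every rare taxon is a
singleton. No abundance filtering or rarefaction is applied by default;
`alpha_diversity(rarefy =, seed =)` offers seeded subsampling for parity
experiments.

## Ensemble network inference

Associations between dominant taxa are scored by three metrics on relative
abundances — Pearson, Spearman, Bray–Curtis similarity — each with a
permutation p-value (one shared sample permutation per draw; two-sided for
the correlations, one-sided for the similarity). The three p-values per
pair are merged with Brown's method: Fisher's statistic
$T = -2\sum \ln p_i$ referred to a scaled $\chi^2$ with
$c = \mathrm{Var}/2\mathrm{E}$, $\mathrm{df} = 2\mathrm{E}^2/\mathrm{Var}$,
where the covariance between $-2\ln p_i$ terms is estimated from the
empirical correlation of the metric score vectors via the Kost–McDermott
polynomial $3.263\rho + 0.710\rho^2 + 0.027\rho^3$. At zero correlation
this is exactly Fisher's method (asserted numerically in the tests); at
perfect correlation two identical p-values merge to themselves. Merged
p-values are BH-adjusted across pairs, and an edge is kept when
$|\rho| > 0.6$ **and** $q < 0.01$, signed by $\rho$. The ensemble uses
three metrics but `browns_merge()` accepts any number $\ge 2$.

Two readings of the dominance filter exist — mean relative abundance
across samples, or exceeding the threshold in every sample — and the mean
is the default (`per_sample_min = TRUE` gives the stricter one). Modules
come from greedy modularity maximization (`igraph::cluster_fast_greedy`);
keystone taxa are the nodes of highest within-module degree ("module
hubs"). With three replicates per treatment a per-group network is
statistically fragile; the package warns below five samples, and its own
network tests use 20 samples.

## The synthetic-data generator

The generator exists so that every downstream stage has a ground-truth
recovery test. It emulates a conservation-tillage soil study design: four
treatment groups × three replicates, a few hundred OTUs, library depths in
the low thousands, with phylogenetically conserved habitat preferences.
Counts are a single multinomial draw per sample at exactly `depth` reads —
sampling noise enters once, and per-sample totals are exact by
construction.

Three design choices deserve explanation, because each was forced by a
quantitative failure of the simpler alternative:

**Demographic drift noise.** Replicates that are multinomial draws from
one fixed weight vector are far *more* similar than any richness- and
abundance-preserving null expects: RC~bray~ pins at −1 for every pair and
no regime is recoverable. Real field replicates differ compositionally.
Every regime therefore multiplies its base weights by per-sample
log-normal noise of width `drift_sd` (default 0.2, chosen so that under
the neutral regime RC~bray~ straddles 0 and the modal label is drift).
This knob sets the generator's ratio of observed to null turnover and is
deliberately *between* the extremes: at 0 all regimes look homogenized, at
0.5 all look dispersal-limited.

**Tree shape.** On a pure Yule tree the Brownian trait's sister-tip
variance is only a few-fold smaller than its tree-wide variance, so a
Gaussian habitat filter of any width either splits sister pairs (a patchy,
weakly clustered retained set) or retains half the tree. Real 97%-OTU
trees are different: patristic distances are bimodal — tiny within
genus-level clusters, large and homogeneous between them. Scenario
phylogenies therefore default to a two-level "star-cluster" tree
(`simulate_cluster_tree()`): Yule tufts of height 0.02 on a star backbone
of height 1, three tips per cluster. `simulate_tree()` still provides the
plain Yule model, and `tree_model = "yule"` selects it in a scenario.

**Anchored optima.** The Brownian root state (0) is the *mean* of the tip
trait distribution but typically the trait value of no extant clade; a
filter centred there retains scattered intermediate lineages — communities
that are phylogenetically *over*dispersed. The default shared optimum is
instead the trait value of one seed-chosen anchor taxon, so the filter
retains that taxon's clade neighbourhood. Distinct per-group optima
(numeric `group_optima`) produce between-group variable selection;
coinciding optima produce homogeneous selection, the configuration of
interest here.

The regimes then are: **neutral** (shared log-normal pool, `pool_sdlog`
= 1), **selection** (pool × Gaussian filter of width `selection_strength`,
defaulting to 0.2 × the realized tip-trait sd — strong filtering), and
**dispersal-limited** (each replicate's pool perturbed log-normally with
`pert_sdlog` = 2, mixed with the shared pool by `migration`). The
perturbation vector is drawn for every sample in every regime and simply
unused elsewhere, so `migration = 1` and `selection_strength` → ∞
reproduce neutral *counts* byte-for-byte — the limiting cases are exact,
not approximate.

**Problem sizes.** Neutral-regime calibration runs at 200 taxa and depth
2000 (the default scenario scale). Selection recovery runs at 500 taxa and
depth 1000: the nearest-taxon signal needs *sparse* communities. When most
taxa are present in most samples, shared taxa self-match at distance zero
in both the observed and the null statistic, and the tip-shuffle null loses
its contrast; with per-sample richness well below the pool size, the
filtered community is clustered while its random relabeling is not. This
is also the regime of real OTU tables, where any one sample holds a small
fraction of the regional species pool.

**What the generator does not emulate:** sequencing error, chimeras, PCR
and copy-number bias, compositional covariation between groups, real
phylogenetic uncertainty, or soil chemistry covariates. Recovery tests
passing on these synthetics show that the statistics detect the mechanisms
they are defined to detect under clean conditions — not that any
particular real dataset's labels are correct.

## Numerical choices and degenerate inputs

* Null standard deviations of exactly 0 (identical communities, or a
  community spanning every tip) flag the effect size `NA` with a warning;
  classification excludes such pairs and counts them in `n_excluded`.
* βNTI, ses.MNTD and RC~bray~ canonicalize taxon (and, for RC~bray~,
  sample) order internally, so results are exactly invariant to input
  row/column permutations at a fixed seed.
* RC~bray~ tie detection uses an absolute tolerance of $10^{-12}$ on
  Bray–Curtis values.
* PCoA (classical MDS via `stats::cmdscale`) drops negative eigenvalues
  from variance proportions and reports them in a diagnostics field.
* Mantel environmental distances (`env_distance()`) z-score each variable
  before the Euclidean distance, since environmental parameters come in
  incommensurable units; constant variables are dropped.
* Chao1's classic form with no doubletons falls back to
  $S_\mathrm{obs} + F_1(F_1-1)/2$.
* Per-stage seeds derive from one global seed by fixed offsets
  (`stage_seed()`), so any stage can be re-run in isolation and reproduce
  the full-pipeline result.

## A worked recovery example

```{r recovery, eval = FALSE}
sc <- synthetic_scenario(regime = "selection", n_taxa = 500, depth = 1000,
                         seed = 7)
ds <- generate_dataset(sc)
asm <- community_assembly(ds$counts, ds$tree, ds$groups,
                          n_null = 199, seed = 42)
summary(asm)
plot(asm)   # beta-NTI by group context, with the +/-2 thresholds
```

Under this strong shared habitat filter the modal label is homogeneous
selection for every treatment group, with a small stochastic remainder —
the qualitative signature the classifier is designed to recover.

## Known limitations

* βMPD / ses.comdist (basal phylogenetic turnover) is not implemented;
  the package covers the nearest-taxon family only.
* The tip-shuffle null uses the full tree as the species pool; restricted
  or habitat-specific pools are out of scope.
* Correlation networks on three replicates per group — the original design
  scale — are inferentially fragile regardless of implementation; the
  package computes them but warns.
* The generator's regimes are caricatures with one mechanism each;
  mixed-regime datasets (selection in some groups, dispersal limitation in
  others) can be composed manually but have no scenario shortcut.
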