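# microassembly

Quantifies whether microbial communities were assembled by deterministic
processes (environmental selection) or stochastic ones (dispersal and
drift), from nothing more than an OTU count table, a rooted phylogeny and a
sample-to-treatment mapping. Built for soil-microbiome designs of the
"4 treatments × 3 replicates" kind, but agnostic to the actual design.

The core is the two-stage phylogenetic null-model framework:

1. **βMNTD / βNTI** — the abundance-weighted between-community mean nearest
   taxon distance, standardized against a tip-shuffling null:
   βNTI = (βMNTD_obs − mean_null) / sd_null. βNTI > 2 ⇒ variable selection;
   βNTI < −2 ⇒ homogeneous selection.
2. **RC_bray** — for the pairs the phylogenetic test leaves unresolved
   (|βNTI| ≤ 2), the Bray–Curtis Raup–Crick metric ranks observed
   dissimilarity within a richness- and reads-preserving null:
   RC_bray > 0.95 ⇒ dispersal limitation; RC_bray < −0.95 ⇒ homogenizing
   dispersal; otherwise drift.

Around that core the package provides alpha diversity (Good's coverage,
Chao1, ACE, Shannon in bits, Gini–Simpson), Bray–Curtis and unweighted
UniFrac distances with PCoA, Mantel tests, ensemble co-occurrence networks
(Pearson + Spearman + Bray–Curtis similarity, permutation p-values merged
by Brown's method and BH-corrected, edges gated at |ρ| > 0.6 and q < 0.01,
modules and keystone taxa), and a synthetic-data generator with known
assembly regimes so every stage has a ground-truth recovery test. See the
vignette `vignettes/community-assembly-methods.Rmd` for the model details
and design rationale.

## Worked example

Simulate a community dataset under strong shared environmental filtering,
then ask the classifier what assembled it:

```r
library(microassembly)

sc <- synthetic_scenario(regime = "selection", n_taxa = 500, depth = 1000,
                         seed = 7)
ds <- generate_dataset(sc)   # counts (12 x 500), tree, groups, traits

asm <- community_assembly(ds$counts, ds$tree, ds$groups,
                          n_null = 199, seed = 42)
summary(asm)
```

```
Community assembly inference: 66 sample pairs, 199 null draws
  deterministic 87.88% (variable 0.00%, homogeneous 87.88%)
  stochastic    12.12% (dispersal lim. 0.00%, homog. dispersal 1.52%, drift 10.61%)

Within-group process fractions:
   scope n_pairs frac_homogeneous_selection frac_dispersal_limitation
  CntWnt       3                      1.000                         0
 CntWntS       3                      0.667                         0
   CntWt       3                      1.000                         0
  CntWtS       3                      1.000                         0
 frac_drift deterministic_fraction
      0.000                  1.000
      0.333                  0.667
      0.000                  1.000
      0.000                  1.000
```

Of the 66 sample pairs, 87.88% classify as deterministic, all of it
homogeneous selection — the communities are phylogenetically far more
similar than the tip-shuffle null expects, exactly what a strong shared
habitat filter produces. The per-group table shows the same verdict within
each treatment. `asm$pairs` holds the per-pair βMNTD, βNTI, RC_bray and
label; `plot(asm)` draws βNTI by group with the ±2 thresholds.

Alpha diversity for the same data:

```r
head(alpha_diversity(ds$counts)[, c("sample_id", "reads", "observed_otus",
                                    "chao1", "shannon", "simpson")], 3)
```

```
  sample_id reads observed_otus    chao1  shannon  simpson
1  CntWt_r1  1000           120 137.1053 5.944198 0.974390
2  CntWt_r2  1000           109 121.2143 5.891230 0.973840
3  CntWt_r3  1000           118 159.6250 5.853760 0.973442
```

Shannon is in bits; chao1 ≥ observed richness always holds. A
co-occurrence network on a table with enough samples:

```r
net <- cooccurrence_network(counts, rho_threshold = 0.6, q_threshold = 0.01,
                            n_perm = 1000, seed = 42)
net$summary      # nodes, signed links, density, degree, modularity, keystones
```

Real data enter through `read_count_table()`, `read_newick()` and
`read_metadata()`; `run_pipeline(run_config(...))` orchestrates every
stage into TSV outputs with a reproducibility manifest, and
`exec/microassembly` exposes the same steps as shell subcommands
(`simulate`, `alpha`, `beta`, `pcoa`, `assembly`, `network`, `run`).

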