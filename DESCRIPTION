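Package: microassembly
Title: Phylogenetic Null Models, Diversity and Co-Occurrence Networks for
    Microbial Community Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies deterministic versus stochastic assembly of microbial
    communities from an OTU count table and a rooted phylogeny. Implements
    abundance-weighted (beta) mean nearest taxon distances, their standardized
    effect sizes (ses.MNTD, beta-NTI) under tip-shuffling null models, the
    Bray-Curtis-based Raup-Crick metric (RC-bray) with a richness- and
    abundance-preserving null, and the five-way classification of assembly
    processes (variable selection, homogeneous selection, dispersal
    limitation, homogenizing dispersal, drift). Also provides alpha-diversity
    estimators (Good's coverage, Chao1, ACE, Shannon, Gini-Simpson),
    Bray-Curtis and unweighted UniFrac distances with principal coordinates
    analysis, ensemble co-occurrence network inference (Pearson, Spearman and
    Bray-Curtis similarity merged by Brown's method with Benjamini-Hochberg
    correction), network topology and module/keystone reporting, and a
    synthetic-data generator with known assembly regimes for ground-truth
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    mclust,
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
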