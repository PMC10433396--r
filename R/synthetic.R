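# Synthetic communities with known assembly regimes.
#
# The generator mirrors the study design it stands in for: four treatment
# groups x three replicates (12 samples), a few hundred OTUs, and
# multinomial sampling at fixed library depth. Habitat preference is a
# Brownian trait on the phylogeny; a Gaussian habitat filter around a
# clade-anchored optimum produces the phylogenetically clustered
# communities that beta-NTI detects. Every sample additionally receives
# multiplicative log-normal "demographic drift" noise, so replicates differ
# compositionally the way field replicates do — without it, multinomial
# resampling of one fixed weight vector yields near-identical replicates
# whose turnover sits far below every null model's.
#
# The default phylogeny for scenarios is a two-level "star-cluster" tree:
# many small Yule tufts (OTUs within a genus-like cluster) hanging from a
# uniform star backbone (distant lineages). This mirrors the branch-length
# profile of 97%-identity OTU trees — tiny within-cluster distances, large
# homogeneous between-cluster distances — which is what makes
# nearest-taxon statistics informative. A plain Yule tree is available too
# (and is the shape [simulate_tree()] provides).

#' Define a synthetic community scenario
#'
#' A scenario fixes everything about a simulated dataset: the phylogeny,
#' the sampling design, the library depth, the assembly regime and its
#' strength, and the seed. Replaying a scenario reproduces the dataset
#' byte-for-byte.
#'
#' Regimes (all share a log-normal metacommunity pool and per-sample
#' demographic drift noise of width `drift_sd`):
#' * `"selection"` — sampling weights are the pool weights multiplied by a
#'   Gaussian habitat filter `exp(-(trait - optimum)^2 / (2 sigma^2))`,
#'   `sigma = selection_strength`. As `selection_strength -> Inf` this
#'   reduces exactly to the neutral regime. A shared optimum (the default:
#'   the trait value of one anchor taxon) yields homogeneous selection;
#'   distinct per-group optima add variable selection between groups.
#' * `"neutral"` — all samples draw from the shared pool.
#' * `"dispersal_limited"` — each replicate's pool is perturbed by an
#'   independent log-normal factor (width `pert_sdlog`) and mixed with the
#'   shared pool in proportion `migration`; `migration = 1` reduces exactly
#'   to neutral.
#'
#' @param n_taxa number of OTUs (>= 3).
#' @param n_groups number of treatment groups.
#' @param reps_per_group replicates per group (>= 2).
#' @param depth reads per sample (> 0); per-sample totals equal `depth`
#'   exactly (multinomial draw, no rarefaction).
#' @param regime `"selection"`, `"neutral"` or `"dispersal_limited"`.
#' @param selection_strength width (sd) of the Gaussian habitat filter in
#'   trait units; smaller = stronger filtering. Default `NULL` means
#'   0.2 x the realized tip-trait standard deviation — a strong filter
#'   retaining roughly the fifth of the phylogeny nearest the optimum.
#' @param trait_sigma Brownian-motion rate of the habitat trait.
#' @param group_optima numeric vector of one trait optimum per group
#'   (selection regime); default `NULL` anchors a single shared optimum at
#'   the trait value of a randomly chosen taxon.
#' @param migration mixing weight of the shared pool in the
#'   dispersal-limited regime, in `[0, 1]`.
#' @param drift_sd sd (log scale) of the per-sample demographic drift
#'   noise; 0 disables it.
#' @param pool_sdlog sd (log scale) of the shared log-normal pool.
#' @param pert_sdlog sd (log scale) of the replicate pool perturbation
#'   (dispersal-limited regime).
#' @param tree_model `"star_cluster"` (default; see
#'   [simulate_cluster_tree()]) or `"yule"` ([simulate_tree()]).
#' @param cluster_size,backbone_height,tuft_height star-cluster tree shape
#'   parameters.
#' @param group_labels optional group names; defaults to the four tillage
#'   treatment codes (CntWt, CntWntS, CntWtS, CntWnt) when `n_groups == 4`.
#' @param seed integer RNG seed; stage seeds for tree, trait, pool and
#'   sampling are derived from it with fixed offsets (see [stage_seed()]).
#' @return an object of class `"synthetic_scenario"`.
#' @export
synthetic_scenario <- function(n_taxa = 200L, n_groups = 4L,
                               reps_per_group = 3L, depth = 2000L,
                               regime = c("selection", "neutral",
                                          "dispersal_limited"),
                               selection_strength = NULL, trait_sigma = 1,
                               group_optima = NULL, migration = 0.3,
                               drift_sd = 0.2, pool_sdlog = 1,
                               pert_sdlog = 2,
                               tree_model = c("star_cluster", "yule"),
                               cluster_size = 3L, backbone_height = 1,
                               tuft_height = 0.02, group_labels = NULL,
                               seed = 1L) {
  regime <- match.arg(regime)
  tree_model <- match.arg(tree_model)
  if (n_taxa < 3L) stopf("n_taxa must be >= 3")
  if (depth < 1L) stopf("depth must be > 0")
  if (reps_per_group < 2L) stopf("reps_per_group must be >= 2")
  if (migration < 0 || migration > 1) stopf("migration must be in [0, 1]")
  if (drift_sd < 0) stopf("drift_sd must be >= 0")
  if (regime == "selection") {
    if (!is.null(group_optima) && length(group_optima) != n_groups)
      stopf("group_optima must give one trait optimum per group (%d given, %d groups)",
            length(group_optima), n_groups)
    if (!is.null(selection_strength) && selection_strength <= 0)
      stopf("selection_strength must be > 0")
  }
  if (is.null(group_labels)) {
    group_labels <- if (n_groups == 4L) c("CntWt", "CntWntS", "CntWtS", "CntWnt")
                    else paste0("G", seq_len(n_groups))
  }
  if (length(group_labels) != n_groups)
    stopf("need %d group labels", n_groups)
  structure(list(n_taxa = as.integer(n_taxa), n_groups = as.integer(n_groups),
                 reps_per_group = as.integer(reps_per_group),
                 depth = as.integer(depth), regime = regime,
                 selection_strength = selection_strength,
                 trait_sigma = trait_sigma, group_optima = group_optima,
                 migration = migration, drift_sd = drift_sd,
                 pool_sdlog = pool_sdlog, pert_sdlog = pert_sdlog,
                 tree_model = tree_model,
                 cluster_size = as.integer(cluster_size),
                 backbone_height = backbone_height,
                 tuft_height = tuft_height,
                 group_labels = group_labels, seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Tips are labelled `OTU0001`, `OTU0002`, ... and branch lengths are in
#' expected-substitution units (birth rate 1). Deterministic for a fixed
#' seed.
#'
#' @param n_taxa number of tips (>= 3).
#' @param seed RNG seed.
#' @param ultrametric if `TRUE` (default) simulate a clock-like birth
#'   process ([ape::rphylo]); otherwise draw a random topology with
#'   exponential branch lengths.
#' @return an [ape::phylo] object.
#' @export
simulate_tree <- function(n_taxa, seed = 1L, ultrametric = TRUE) {
  if (n_taxa < 3L) stopf("n_taxa must be >= 3")
  set.seed(seed)
  tree <- if (ultrametric) ape::rphylo(n_taxa, birth = 1, death = 0)
          else ape::rtree(n_taxa)
  tree$tip.label <- sprintf("OTU%04d", seq_len(n_taxa))
  validate_phylogeny(tree)
}

#' Simulate a star-cluster phylogeny
#'
#' A two-level tree emulating the branch-length profile of an OTU tree:
#' `n_taxa / cluster_size` small Yule tufts of height `tuft_height`
#' (OTUs within a genus-like cluster) attached to a star backbone of
#' uniform branch length `backbone_height` (distant lineages). Patristic
#' distances are therefore bimodal: tiny within clusters, about
#' `2 * backbone_height` between them.
#'
#' @param n_taxa number of tips (>= 4).
#' @param cluster_size tips per cluster (>= 2; the last cluster absorbs the
#'   remainder).
#' @param backbone_height branch length from the root to each cluster.
#' @param tuft_height height of each within-cluster subtree.
#' @param seed RNG seed.
#' @return an [ape::phylo] object with tips `OTU0001`, ...
#' @export
simulate_cluster_tree <- function(n_taxa, cluster_size = 3L,
                                  backbone_height = 1, tuft_height = 0.02,
                                  seed = 1L) {
  if (n_taxa < 4L) stopf("n_taxa must be >= 4")
  if (cluster_size < 2L) stopf("cluster_size must be >= 2")
  k <- n_taxa %/% cluster_size
  if (k < 2L) stopf("need at least 2 clusters; lower cluster_size")
  set.seed(seed)
  backbone <- ape::stree(k, type = "star")
  backbone$edge.length <- rep(backbone_height, k)
  tufts <- lapply(seq_len(k), function(i) {
    nt <- if (i == k) n_taxa - cluster_size * (k - 1L) else cluster_size
    tf <- ape::rphylo(max(nt, 2L), birth = 1, death = 0)
    tf$edge.length <- tf$edge.length /
      max(ape::node.depth.edgelength(tf)) * tuft_height
    tf$tip.label <- paste0("c", i, "_", tf$tip.label)
    tf
  })
  tree <- backbone
  for (i in k:1)
    tree <- ape::bind.tree(tree, tufts[[i]],
                           where = match(backbone$tip.label[i], tree$tip.label))
  tree$tip.label <- sprintf("OTU%04d", seq_along(tree$tip.label))
  validate_phylogeny(tree)
}

#' Evolve a continuous habitat trait along a phylogeny
#'
#' Brownian motion with rate `trait_sigma`, root state 0. Tip variance
#' grows with root-to-tip distance, so close relatives share habitat
#' preferences — the phylogenetic signal that makes nearest-taxon
#' statistics informative.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param trait_sigma Brownian rate (>= 0; 0 collapses every tip to the
#'   root state).
#' @param seed RNG seed.
#' @return named numeric vector of tip trait values.
#' @export
evolve_trait <- function(tree, trait_sigma = 1, seed = 1L) {
  if (trait_sigma < 0) stopf("trait_sigma must be >= 0")
  set.seed(seed)
  if (trait_sigma == 0)
    return(stats::setNames(rep(0, length(tree$tip.label)), tree$tip.label))
  tr <- ape::rTraitCont(tree, model = "BM", sigma = trait_sigma)
  stats::setNames(as.numeric(tr), names(tr))
}

#' Assemble replicate communities under a scenario
#'
#' Per sample, sampling weights are the regime's base weights (see
#' [synthetic_scenario()]) times a log-normal demographic drift factor;
#' counts are one multinomial draw of `depth` reads, so per-sample totals
#' equal `depth` exactly. The replicate pool perturbation is drawn for
#' every sample regardless of regime (and simply unused outside the
#' dispersal-limited regime), so the limiting cases `migration = 1` and
#' `selection_strength -> Inf` reproduce the neutral regime's counts
#' exactly, not just in distribution.
#'
#' @param tree [ape::phylo] over the taxa.
#' @param traits named trait vector from [evolve_trait()].
#' @param scenario a [synthetic_scenario()].
#' @return list of class `"synthetic_dataset"` with elements `counts`
#'   (samples x taxa), `tree`, `groups` (named character), `traits`,
#'   `regime`, `optima` (realized per-group optima, selection regime),
#'   and `scenario`.
#' @export
assemble_communities <- function(tree, traits, scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  taxa <- tree$tip.label
  traits <- traits[taxa]
  if (anyNA(traits)) stopf("traits missing for some tree tips")
  n_taxa <- length(taxa)
  n_samples <- scenario$n_groups * scenario$reps_per_group

  set.seed(stage_seed(scenario$seed, "pool"))
  pool <- stats::rlnorm(n_taxa, meanlog = 0, sdlog = scenario$pool_sdlog)
  anchor <- sample.int(n_taxa, 1L)

  optima <- NULL
  sigma <- NULL
  if (scenario$regime == "selection") {
    optima <- if (is.null(scenario$group_optima))
      rep(traits[[anchor]], scenario$n_groups) else scenario$group_optima
    sigma <- if (is.null(scenario$selection_strength))
      0.2 * stats::sd(traits) else scenario$selection_strength
    if (sigma <= 0) stopf("degenerate habitat filter (zero trait variation)")
  }

  groups <- rep(scenario$group_labels, each = scenario$reps_per_group)
  sample_ids <- paste0(groups, "_r", rep(seq_len(scenario$reps_per_group),
                                         times = scenario$n_groups))
  set.seed(stage_seed(scenario$seed, "sampling"))
  counts <- matrix(0L, n_samples, n_taxa, dimnames = list(sample_ids, taxa))
  for (s in seq_len(n_samples)) {
    g <- (s - 1L) %/% scenario$reps_per_group + 1L
    pert <- stats::rlnorm(n_taxa, 0, scenario$pert_sdlog)
    base <- switch(scenario$regime,
      neutral = pool,
      selection = pool * exp(-(traits - optima[g])^2 / (2 * sigma^2)),
      dispersal_limited =
        scenario$migration * pool + (1 - scenario$migration) * pool * pert)
    w <- base * stats::rlnorm(n_taxa, 0, scenario$drift_sd)
    if (sum(w) <= 0) stopf("habitat filter left no taxon with positive weight")
    counts[s, ] <- as.integer(stats::rmultinom(1L, scenario$depth, w / sum(w)))
  }
  structure(list(counts = validate_counts(counts), tree = tree,
                 groups = stats::setNames(groups, sample_ids),
                 traits = traits, regime = scenario$regime,
                 optima = optima, scenario = scenario),
            class = "synthetic_dataset")
}

#' Generate a full synthetic dataset
#'
#' Simulates the phylogeny (per `scenario$tree_model`), evolves the habitat
#' trait and assembles the communities, with stage seeds derived from the
#' scenario seed.
#'
#' @param scenario a [synthetic_scenario()].
#' @return a `"synthetic_dataset"` list (see [assemble_communities()]).
#' @export
generate_dataset <- function(scenario = synthetic_scenario()) {
  tree <- if (scenario$tree_model == "star_cluster")
    simulate_cluster_tree(scenario$n_taxa, scenario$cluster_size,
                          scenario$backbone_height, scenario$tuft_height,
                          seed = stage_seed(scenario$seed, "tree"))
  else simulate_tree(scenario$n_taxa, seed = stage_seed(scenario$seed, "tree"))
  traits <- evolve_trait(tree, scenario$trait_sigma,
                         seed = stage_seed(scenario$seed, "trait"))
  assemble_communities(tree, traits, scenario)
}

#' Write a synthetic dataset to disk
#'
#' Writes `counts.tsv`, `tree.nwk`, `metadata.tsv` and a `manifest.json`
#' recording the scenario parameters and seed, so the dataset can be
#' regenerated byte-identically.
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir output directory (created if missing).
#' @param force overwrite existing files.
#' @return invisibly, the `"synthetic_dataset"` with a `files` element
#'   added.
#' @export
write_dataset <- function(scenario, dir, force = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- stats::setNames(
    file.path(dir, c("counts.tsv", "tree.nwk", "metadata.tsv", "manifest.json")),
    c("counts", "tree", "metadata", "manifest"))
  exists <- files[file.exists(files)]
  if (length(exists) && !force)
    stopf("refusing to overwrite %s (use force = TRUE)",
          paste(basename(exists), collapse = ", "))
  ds <- generate_dataset(scenario)
  write_count_table(ds$counts, files[["counts"]])
  write_newick(ds$tree, files[["tree"]])
  write_metadata(ds$groups, files[["metadata"]])
  manifest <- Filter(Negate(is.null), unclass(ds$scenario))
  manifest$package_version <- as.character(utils::packageVersion("microassembly"))
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  ds$files <- files
  invisible(ds)
}

#' Re-create a synthetic scenario from a manifest
#'
#' @param path path to a `manifest.json` written by [write_dataset()].
#' @return a `"synthetic_scenario"`.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  keep <- intersect(names(m), names(formals(synthetic_scenario)))
  do.call(synthetic_scenario, m[keep])
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("Synthetic scenario: %s regime\n", x$regime))
  cat(sprintf("  %d taxa (%s tree), %d groups x %d reps, depth %d, seed %d\n",
              x$n_taxa, x$tree_model, x$n_groups, x$reps_per_group, x$depth,
              x$seed))
  if (x$regime == "selection")
    cat(sprintf("  habitat filter sd %s, optima %s\n",
                if (is.null(x$selection_strength)) "auto (0.2 x trait sd)"
                else format(x$selection_strength),
                if (is.null(x$group_optima)) "shared (anchored)"
                else paste(signif(x$group_optima, 3), collapse = ", ")))
  if (x$regime == "dispersal_limited")
    cat(sprintf("  migration %.3g, perturbation sdlog %.3g\n", x$migration,
                x$pert_sdlog))
  cat(sprintf("  pool sdlog %.3g, demographic drift sd %.3g\n",
              x$pool_sdlog, x$drift_sd))
  invisible(x)
}
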