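# One-command orchestration: simulate (or read) -> diversity -> assembly ->
# network, with a manifest that makes every stochastic output reproducible.

#' Build a pipeline configuration
#'
#' Either `counts`/`tree`/`metadata` paths or a `scenario` must be given.
#' Defaults follow the conventional analysis settings: 999 null draws and
#' permutations for the null models and the Mantel test, 1000 permutations
#' for the network ensemble, 0.5% dominance filter, edge gates
#' `|rho| > 0.6` and `q < 0.01`.
#'
#' @param counts,tree,metadata input file paths (TSV / Newick / TSV).
#' @param scenario a [synthetic_scenario()] to simulate instead of reading.
#' @param out_dir output directory.
#' @param seed global seed; stage seeds are derived with fixed offsets.
#' @param n_null null draws for beta-NTI and RC_bray.
#' @param n_perm permutations for network p-values.
#' @param dominance_threshold,rho_threshold,q_threshold network parameters.
#' @param beta_metric `"braycurtis"` or `"unifrac"` for the ordination.
#' @param network_scope `"all"` (one network over all samples) or
#'   `"per_group"` (one per treatment group).
#' @param prune drop count-table taxa absent from the tree.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(counts = NULL, tree = NULL, metadata = NULL,
                       scenario = NULL, out_dir = "pipeline_out", seed = 42L,
                       n_null = 999L, n_perm = 1000L,
                       dominance_threshold = 0.005, rho_threshold = 0.6,
                       q_threshold = 0.01,
                       beta_metric = c("braycurtis", "unifrac"),
                       network_scope = c("all", "per_group"),
                       prune = FALSE) {
  beta_metric <- match.arg(beta_metric)
  network_scope <- match.arg(network_scope)
  if (is.null(scenario) && (is.null(counts) || is.null(metadata)))
    stopf("give either input paths (counts, metadata[, tree]) or a scenario")
  if (is.null(scenario) && is.null(tree))
    stopf("a tree is required for UniFrac and assembly inference")
  structure(list(counts = counts, tree = tree, metadata = metadata,
                 scenario = scenario, out_dir = out_dir,
                 seed = as.integer(seed), n_null = as.integer(n_null),
                 n_perm = as.integer(n_perm),
                 dominance_threshold = dominance_threshold,
                 rho_threshold = rho_threshold, q_threshold = q_threshold,
                 beta_metric = beta_metric, network_scope = network_scope,
                 prune = prune),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; a `scenario` block
#' mirrors [synthetic_scenario()].
#'
#' @param path YAML file.
#' @return a `"run_config"`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$scenario)) y$scenario <- do.call(synthetic_scenario, y$scenario)
  do.call(run_config, y)
}

#' @keywords internal
#' @noRd
log_stage <- function(stage, t0, ...) {
  msg <- paste(sprintf("%s=%s", names(c(...)), c(...)), collapse = " ")
  message(sprintf("[%s] %s elapsed=%.1fs", stage, msg,
                  as.numeric(proc.time()[3L] - t0)))
}

#' Run the full pipeline
#'
#' Stages: load or simulate inputs; alpha diversity (+ group summary); beta
#' diversity and PCoA; community-assembly inference; co-occurrence
#' network(s). Every stage's outputs are written as TSV (plus SIF/GraphML
#' for networks) under `config$out_dir`, together with `run_manifest.json`
#' recording parameters, seeds and the package version. Re-running with the
#' same config reproduces all stochastic outputs exactly.
#'
#' @param config a [run_config()] or path to a YAML config.
#' @return invisibly, a list with the in-memory results
#'   (`alpha`, `ordination`, `assembly`, `networks`, `paths`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[3L]

  if (!is.null(config$scenario)) {
    ds <- generate_dataset(config$scenario)
    counts <- ds$counts; tree <- ds$tree; groups <- ds$groups
  } else {
    counts <- read_count_table(config$counts)
    tree <- read_newick(config$tree)
    groups <- read_metadata(config$metadata)
  }
  counts <- match_tree_taxa(counts, tree, prune = config$prune)
  groups <- match_sample_groups(counts, groups)
  log_stage("inputs", t0, samples = nrow(counts), taxa = ncol(counts))

  paths <- c()
  out <- function(name) file.path(config$out_dir, name)

  alpha <- alpha_diversity(counts)
  write_table(alpha, out("alpha.tsv"))
  write_table(alpha_group_summary(alpha, groups), out("alpha_groups.tsv"))
  log_stage("alpha", t0, samples = nrow(alpha))

  dm <- if (config$beta_metric == "unifrac") unweighted_unifrac(counts, tree)
        else bray_curtis(counts)
  write_table(dist_to_matrix(dm), out("beta_distance.tsv"), row_names = TRUE)
  ord <- pcoa(dm, k = 2L)
  ord_df <- data.frame(sample_id = rownames(ord$points), ord$points,
                       group = groups[rownames(ord$points)])
  write_table(ord_df, out("pcoa.tsv"))
  log_stage("beta", t0, metric = config$beta_metric)

  asm <- community_assembly(counts, tree, groups, n_null = config$n_null,
                            seed = config$seed)
  write_table(asm$pairs, out("pairwise_assembly.tsv"))
  write_table(asm$ses_mntd, out("ses_mntd.tsv"))
  write_table(rbind(asm$summary_overall, asm$summary_within),
              out("process_summary.tsv"))
  log_stage("assembly", t0, pairs = nrow(asm$pairs), nulls = config$n_null)

  scopes <- if (config$network_scope == "per_group") {
    stats::setNames(lapply(unique(groups), function(g)
      counts[names(groups)[groups == g], , drop = FALSE]), unique(groups))
  } else list(all = counts)
  networks <- lapply(names(scopes), function(nm) {
    net <- withCallingHandlers(
      cooccurrence_network(scopes[[nm]],
                           dominance_threshold = config$dominance_threshold,
                           rho_threshold = config$rho_threshold,
                           q_threshold = config$q_threshold,
                           n_perm = config$n_perm, seed = config$seed),
      warning = function(w) {
        message(sprintf("[network:%s] %s", nm, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    write_table(net$edges, out(sprintf("edges_%s.tsv", nm)))
    write_edge_list(graph_edges(net$graph), out(sprintf("edges_%s.sif", nm)))
    if (igraph::vcount(net$graph) > 0L)
      write_graphml(net$graph, out(sprintf("network_%s.graphml", nm)))
    s <- net$summary
    write_table(data.frame(parameter = names(unclass(s))[1:9],
                           value = unlist(unclass(s)[1:9], use.names = FALSE)),
                out(sprintf("network_summary_%s.tsv", nm)))
    net
  })
  names(networks) <- names(scopes)
  log_stage("network", t0, scopes = length(networks))

  manifest <- list(
    seed = config$seed, n_null = config$n_null, n_perm = config$n_perm,
    dominance_threshold = config$dominance_threshold,
    rho_threshold = config$rho_threshold, q_threshold = config$q_threshold,
    beta_metric = config$beta_metric, network_scope = config$network_scope,
    inputs = if (is.null(config$scenario))
      list(counts = config$counts, tree = config$tree,
           metadata = config$metadata)
    else unclass(config$scenario),
    package_version = as.character(utils::packageVersion("microassembly")))
  jsonlite::write_json(manifest, out("run_manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(alpha = alpha, ordination = ord, assembly = asm,
                 networks = networks, out_dir = config$out_dir))
}
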