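# Ensemble co-occurrence network inference.
#
# For every pair of dominant taxa three association metrics are computed on
# relative abundances across samples — Pearson correlation, Spearman
# correlation and Bray-Curtis similarity (1 - dissimilarity) — each with a
# permutation p-value. The per-metric p-values are merged with Brown's
# method (Fisher's method corrected for dependence between the metrics via
# the Kost-McDermott covariance polynomial) and corrected across pairs with
# Benjamini-Hochberg. An edge is kept when |Spearman rho| exceeds the
# coefficient gate and the BH-adjusted merged p passes the significance
# gate; the edge sign is the sign of rho.

#' Keep dominant taxa
#'
#' Retains taxa whose mean relative abundance across all samples exceeds
#' `threshold` (default 0.5%). With `per_sample_min = TRUE` a taxon must
#' instead exceed the threshold in every sample.
#'
#' @param counts count matrix (samples x taxa).
#' @param threshold relative-abundance threshold in `(0, 1)`.
#' @param per_sample_min require the threshold in every sample.
#' @return filtered count matrix.
#' @export
filter_dominant <- function(counts, threshold = 0.005, per_sample_min = FALSE) {
  counts <- validate_counts(counts)
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  rel <- rel_abundance(counts)
  keep <- if (per_sample_min) apply(rel, 2L, min) > threshold
          else colMeans(rel) > threshold
  if (!any(keep))
    stopf("no taxon exceeds relative abundance %g; try a lower threshold", threshold)
  counts[, keep, drop = FALSE]
}

#' @keywords internal
#' @noRd
bc_similarity_cross <- function(a, b) {
  # 1 - Bray-Curtis between column i of a and column j of b, for all (i, j)
  pa <- ncol(a); pb <- ncol(b)
  out <- matrix(0, pa, pb)
  ta <- colSums(a); tb <- colSums(b)
  for (i in seq_len(pa)) {
    out[i, ] <- 1 - colSums(abs(a[, i] - b)) / (ta[i] + tb)
  }
  out
}

#' Pairwise association metrics between taxa
#'
#' Pearson r, Spearman rho and Bray-Curtis similarity computed on relative
#' abundances across samples, for every unordered taxon pair. All three are
#' oriented so that larger means more associated. Taxa with zero variance
#' across samples have undefined correlations; their pairs are excluded and
#' listed in the `excluded_taxa` attribute.
#'
#' @param counts count matrix (samples x taxa), >= 4 samples.
#' @return data frame (`taxon_a`, `taxon_b`, `pearson_r`, `spearman_rho`,
#'   `bray_curtis_sim`) with attribute `excluded_taxa`.
#' @export
pairwise_metrics <- function(counts) {
  counts <- validate_counts(counts)
  if (nrow(counts) < 4L) stopf("correlations need at least 4 samples")
  rel <- rel_abundance(counts)
  zero_var <- apply(rel, 2L, function(v) stats::var(v) == 0)
  excl <- colnames(rel)[zero_var]
  rel <- rel[, !zero_var, drop = FALSE]
  if (ncol(rel) < 2L) stopf("fewer than 2 taxa with variation across samples")
  pr <- stats::cor(rel, method = "pearson")
  sr <- stats::cor(rel, method = "spearman")
  bc <- bc_similarity_cross(rel, rel)
  p <- ncol(rel)
  idx <- which(upper.tri(pr), arr.ind = TRUE)
  out <- data.frame(
    taxon_a = colnames(rel)[idx[, 1L]],
    taxon_b = colnames(rel)[idx[, 2L]],
    pearson_r = pr[idx], spearman_rho = sr[idx], bray_curtis_sim = bc[idx],
    stringsAsFactors = FALSE)
  attr(out, "excluded_taxa") <- excl
  out
}

#' Permutation p-values for the association metrics
#'
#' Null: per permutation, one taxon's profile is permuted across samples
#' (one shared sample permutation per draw); two-sided for the correlations
#' (`|null| >= |obs|`), one-sided (greater) for Bray-Curtis similarity,
#' with the add-one rule `p = (1 + #extreme) / (1 + n_perm)`.
#'
#' @param counts count matrix restricted to the taxa of interest.
#' @param n_perm permutations (>= 99; default 1000).
#' @param seed RNG seed.
#' @return data frame aligned with [pairwise_metrics()]: `taxon_a`,
#'   `taxon_b`, `p_pearson`, `p_spearman`, `p_bray`.
#' @export
permutation_pvalues <- function(counts, n_perm = 1000L, seed = 1L) {
  counts <- validate_counts(counts)
  if (n_perm < 99L) stopf("n_perm must be >= 99")
  rel <- rel_abundance(counts)
  zero_var <- apply(rel, 2L, function(v) stats::var(v) == 0)
  rel <- rel[, !zero_var, drop = FALSE]
  n <- nrow(rel)
  obs_p <- abs(stats::cor(rel, method = "pearson"))
  obs_s <- abs(stats::cor(rel, method = "spearman"))
  obs_b <- bc_similarity_cross(rel, rel)
  hits_p <- hits_s <- hits_b <- matrix(0, ncol(rel), ncol(rel))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    rp <- rel[perm, , drop = FALSE]
    np <- abs(stats::cor(rel, rp, method = "pearson"))
    ns <- abs(stats::cor(rel, rp, method = "spearman"))
    nb <- bc_similarity_cross(rel, rp)
    hits_p <- hits_p + (np >= obs_p)
    hits_s <- hits_s + (ns >= obs_s)
    hits_b <- hits_b + (nb >= obs_b)
  }
  idx <- which(upper.tri(obs_p), arr.ind = TRUE)
  data.frame(
    taxon_a = colnames(rel)[idx[, 1L]],
    taxon_b = colnames(rel)[idx[, 2L]],
    p_pearson = (1 + hits_p[idx]) / (1 + n_perm),
    p_spearman = (1 + hits_s[idx]) / (1 + n_perm),
    p_bray = (1 + hits_b[idx]) / (1 + n_perm),
    stringsAsFactors = FALSE)
}

#' Merge dependent p-values with Brown's method
#'
#' Fisher's statistic `T = -2 sum log p_i` has mean `2k` under the null; for
#' dependent tests its variance is `4k + 2 sum_{i<j} cov_ij`, with `cov_ij`
#' approximated from the correlation of the underlying statistics by the
#' Kost-McDermott polynomial
#' `cov(rho) = 3.263 rho + 0.710 rho^2 + 0.027 rho^3`. The merged p-value is
#' the upper tail of the scaled chi-square `c * chisq(df)` with
#' `c = Var / (2 E)` and `df = 2 E^2 / Var` at `T`. With zero correlations
#' this is exactly Fisher's method.
#'
#' @param pvalues numeric vector (one test per metric, `k >= 2`) or matrix
#'   (rows = tests to merge, columns = metrics), all values in `(0, 1]`.
#' @param metric_correlations `k x k` correlation matrix of the underlying
#'   statistics.
#' @return merged p-value(s), one per row.
#' @export
browns_merge <- function(pvalues, metric_correlations) {
  pm <- if (is.matrix(pvalues)) pvalues else matrix(pvalues, nrow = 1L)
  k <- ncol(pm)
  if (k < 2L) stopf("Brown's method needs at least 2 p-values")
  if (any(pm <= 0) || any(pm > 1)) stopf("p-values must be in (0, 1]")
  r <- as.matrix(metric_correlations)
  if (!all(dim(r) == k)) stopf("metric_correlations must be %d x %d", k, k)
  kost <- function(rho) 3.263 * rho + 0.710 * rho^2 + 0.027 * rho^3
  covsum <- sum(kost(r[upper.tri(r)]))
  e <- 2 * k
  v <- 4 * k + 2 * covsum
  cc <- v / (2 * e)
  df <- 2 * e^2 / v
  tstat <- -2 * rowSums(log(pm))
  stats::pchisq(tstat / cc, df = df, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment ([stats::p.adjust] with
#' `method = "BH"`).
#'
#' @param pvalues numeric vector in `(0, 1]`; may be empty.
#' @return q-values, same length.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0L))
  if (any(pvalues <= 0) || any(pvalues > 1)) stopf("p-values must be in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Full edge table for a count matrix
#'
#' Combines [pairwise_metrics()], [permutation_pvalues()], [browns_merge()]
#' (metric correlations estimated empirically from the three per-pair score
#' vectors) and [bh_adjust()].
#'
#' @inheritParams permutation_pvalues
#' @return data frame with metric scores, per-metric p, `merged_p`, `q` and
#'   `sign` per taxon pair.
#' @export
edge_table <- function(counts, n_perm = 1000L, seed = 1L) {
  met <- pairwise_metrics(counts)
  pv <- permutation_pvalues(counts, n_perm = n_perm, seed = seed)
  stopifnot(identical(met$taxon_a, pv$taxon_a),
            identical(met$taxon_b, pv$taxon_b))
  scores <- as.matrix(met[, c("pearson_r", "spearman_rho", "bray_curtis_sim")])
  mc <- stats::cor(scores)
  pm <- as.matrix(pv[, c("p_pearson", "p_spearman", "p_bray")])
  met$p_pearson <- pv$p_pearson
  met$p_spearman <- pv$p_spearman
  met$p_bray <- pv$p_bray
  met$merged_p <- browns_merge(pm, mc)
  met$q <- bh_adjust(met$merged_p)
  met$sign <- ifelse(met$spearman_rho >= 0, "positive", "negative")
  met
}

#' Build the co-occurrence graph from an edge table
#'
#' Keeps an edge iff `|spearman_rho| > rho_threshold` and
#' `q < q_threshold`; isolated nodes are dropped.
#'
#' @param edges data frame from [edge_table()].
#' @param rho_threshold Spearman magnitude gate (default 0.6).
#' @param q_threshold BH-adjusted significance gate (default 0.01).
#' @return an undirected [igraph::igraph] with edge attributes `sign` and
#'   `spearman_rho`.
#' @export
build_network <- function(edges, rho_threshold = 0.6, q_threshold = 0.01) {
  if (rho_threshold < 0 || rho_threshold >= 1) stopf("rho_threshold must be in [0, 1)")
  if (q_threshold <= 0 || q_threshold > 1) stopf("q_threshold must be in (0, 1]")
  keep <- abs(edges$spearman_rho) > rho_threshold & edges$q < q_threshold
  kept <- edges[keep, , drop = FALSE]
  if (!nrow(kept))
    return(igraph::make_empty_graph(0, directed = FALSE))
  igraph::graph_from_data_frame(
    data.frame(from = kept$taxon_a, to = kept$taxon_b, sign = kept$sign,
               spearman_rho = kept$spearman_rho, stringsAsFactors = FALSE),
    directed = FALSE)
}

#' Network summary from link counts
#'
#' The arithmetic layer of the topology report: given node and signed link
#' counts it derives totals, the positive-link percentage, density
#' `2E / (n (n - 1))` and average degree `2E / n`.
#'
#' @param n_nodes number of nodes.
#' @param positive_links,negative_links signed link counts.
#' @param modularity,n_modules,keystone_taxa optional module statistics.
#' @return object of class `"network_summary"`.
#' @export
network_summary <- function(n_nodes, positive_links, negative_links,
                            modularity = NA_real_, n_modules = NA_integer_,
                            keystone_taxa = character(0L)) {
  total <- positive_links + negative_links
  structure(list(
    n_nodes = as.integer(n_nodes),
    total_links = as.integer(total),
    positive_links = as.integer(positive_links),
    negative_links = as.integer(negative_links),
    pct_positive = if (total > 0) positive_links / total else NA_real_,
    density = if (n_nodes > 1) 2 * total / (n_nodes * (n_nodes - 1)) else 0,
    average_degree = if (n_nodes > 0) 2 * total / n_nodes else 0,
    modularity = modularity, n_modules = n_modules,
    keystone_taxa = keystone_taxa), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("Co-occurrence network summary\n")
  cat(sprintf("  nodes %d, links %d (%d positive = %.2f%%, %d negative)\n",
              x$n_nodes, x$total_links, x$positive_links,
              100 * x$pct_positive, x$negative_links))
  cat(sprintf("  density %.3f, average degree %.3f\n", x$density,
              x$average_degree))
  if (!is.na(x$modularity))
    cat(sprintf("  modularity %.3f, %d module(s) of size >= 3\n",
                x$modularity, x$n_modules))
  if (length(x$keystone_taxa))
    cat("  keystone taxa:", paste(x$keystone_taxa, collapse = ", "), "\n")
  invisible(x)
}

#' Detect modules by greedy modularity maximization
#'
#' @param graph [igraph::igraph].
#' @param seed RNG seed (the greedy algorithm is deterministic; the seed
#'   fixes any tie-breaking done by the backend).
#' @return list of class `"module_partition"`: `membership` (named integer),
#'   `modularity`.
#' @export
detect_modules <- function(graph, seed = 1L) {
  if (igraph::vcount(graph) == 0L)
    return(structure(list(membership = integer(0L), modularity = NA_real_),
                     class = "module_partition"))
  set.seed(seed)
  cl <- igraph::cluster_fast_greedy(graph)
  structure(list(membership = stats::setNames(igraph::membership(cl),
                                              igraph::V(graph)$name),
                 modularity = igraph::modularity(cl)),
            class = "module_partition")
}

#' Keystone taxa (module hubs)
#'
#' Nodes with the highest within-module degree: the number of edges a node
#' has to members of its own module.
#'
#' @param graph [igraph::igraph].
#' @param partition a `"module_partition"` from [detect_modules()].
#' @param top_k number of keystones to report.
#' @return character vector of node names, ordered by within-module degree.
#' @export
keystone_taxa <- function(graph, partition, top_k = 2L) {
  if (igraph::vcount(graph) == 0L) return(character(0L))
  memb <- partition$membership[igraph::V(graph)$name]
  el <- igraph::as_edgelist(graph)
  within <- memb[el[, 1L]] == memb[el[, 2L]]
  deg <- stats::setNames(integer(igraph::vcount(graph)), igraph::V(graph)$name)
  tab <- table(c(el[within, 1L], el[within, 2L]))
  deg[names(tab)] <- as.integer(tab)
  names(sort(deg, decreasing = TRUE))[seq_len(min(top_k, length(deg)))]
}

#' Topology report for a graph
#'
#' @param graph [igraph::igraph] with edge attribute `sign`.
#' @param seed seed for [detect_modules()].
#' @param top_k keystones to report.
#' @return a `"network_summary"`; an empty graph yields a summary of zeros.
#' @export
topology <- function(graph, seed = 1L, top_k = 2L) {
  if (igraph::vcount(graph) == 0L)
    return(network_summary(0L, 0L, 0L))
  sgn <- igraph::E(graph)$sign
  if (is.null(sgn)) sgn <- rep("positive", igraph::ecount(graph))
  part <- detect_modules(graph, seed = seed)
  sizes <- table(part$membership)
  network_summary(
    n_nodes = igraph::vcount(graph),
    positive_links = sum(sgn == "positive"),
    negative_links = sum(sgn == "negative"),
    modularity = part$modularity,
    n_modules = sum(sizes >= 3L),
    keystone_taxa = keystone_taxa(graph, part, top_k = top_k))
}

#' End-to-end co-occurrence network inference
#'
#' [filter_dominant()] then [edge_table()], [build_network()] and
#' [topology()]. With fewer than 5 samples correlation-based networks are
#' statistically fragile; a warning is issued.
#'
#' @param counts count matrix (samples x taxa).
#' @param dominance_threshold mean relative-abundance filter (default 0.005).
#' @param rho_threshold,q_threshold edge gates (defaults 0.6, 0.01).
#' @param n_perm permutations for the per-metric p-values.
#' @param seed global seed.
#' @param top_k keystones to report.
#' @return object of class `"cooccurrence_network"`: `edges` (full edge
#'   table), `graph`, `partition`, `summary`, plus the parameters used.
#' @export
cooccurrence_network <- function(counts, dominance_threshold = 0.005,
                                 rho_threshold = 0.6, q_threshold = 0.01,
                                 n_perm = 1000L, seed = 1L, top_k = 2L) {
  counts <- validate_counts(counts)
  if (nrow(counts) < 5L)
    warning("fewer than 5 samples: correlation-based networks are fragile",
            call. = FALSE)
  dom <- filter_dominant(counts, threshold = dominance_threshold)
  edges <- edge_table(dom, n_perm = n_perm, seed = stage_seed(seed, "network"))
  graph <- build_network(edges, rho_threshold, q_threshold)
  part <- detect_modules(graph, seed = stage_seed(seed, "modules"))
  summ <- topology(graph, seed = stage_seed(seed, "modules"), top_k = top_k)
  structure(list(edges = edges, graph = graph, partition = part,
                 summary = summ, dominance_threshold = dominance_threshold,
                 rho_threshold = rho_threshold, q_threshold = q_threshold,
                 n_perm = n_perm, seed = seed),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("Ensemble co-occurrence network (%d candidate pairs, %d permutations)\n",
              nrow(x$edges), x$n_perm))
  cat(sprintf("  gates: |rho| > %.2f, q < %.2g\n", x$rho_threshold,
              x$q_threshold))
  print(x$summary)
  invisible(x)
}

#' Edges of a network as a SIF-ready data frame
#'
#' @param graph [igraph::igraph] with edge attribute `sign`.
#' @return data frame `taxon_a`, `sign`, `taxon_b`.
#' @export
graph_edges <- function(graph) {
  if (igraph::ecount(graph) == 0L)
    return(data.frame(taxon_a = character(0L), sign = character(0L),
                      taxon_b = character(0L), stringsAsFactors = FALSE))
  el <- igraph::as_edgelist(graph)
  data.frame(taxon_a = el[, 1L],
             sign = substr(igraph::E(graph)$sign, 1L, 3L),
             taxon_b = el[, 2L], stringsAsFactors = FALSE)
}
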