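# Alpha-diversity estimators and beta-diversity distances/ordination.
#
# Shannon defaults to log base 2: with ~4,000 OTUs a Shannon value near 9.5
# is only attainable in bits (ln 4000 ~ 8.3), the convention MOTHUR-style
# reports use. Simpson is reported as Gini-Simpson (1 - sum p^2), so larger
# means more diverse.

#' Good's coverage
#'
#' `1 - F1 / N`: the estimated probability that the next read belongs to an
#' already-observed taxon (`F1` singletons, `N` reads).
#'
#' @param x counts for one sample.
#' @return coverage in `[0, 1]`.
#' @export
goods_coverage <- function(x) {
  x <- x[x > 0]
  n <- sum(x)
  if (n <= 0) stopf("sample has no reads")
  1 - sum(x == 1) / n
}

#' Chao1 richness estimator
#'
#' Bias-corrected by default: `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, which is
#' defined even when no doubletons are observed. The classic estimator
#' `S_obs + F1^2 / (2 F2)` is available with `bias_corrected = FALSE`.
#'
#' @param x counts for one sample.
#' @param bias_corrected use the bias-corrected form (default).
#' @return estimated richness, `>= S_obs`.
#' @export
chao1 <- function(x, bias_corrected = TRUE) {
  x <- x[x > 0]
  if (!length(x)) stopf("sample has no reads")
  s_obs <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (bias_corrected) s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  else if (f2 > 0) s_obs + f1^2 / (2 * f2)
  else s_obs + f1 * (f1 - 1) / 2  # classic form's standard F2=0 fallback
}

#' ACE richness estimator
#'
#' Abundance-based coverage estimator with rare/abundant split at
#' `rare_cutoff` reads:
#' `S_abund + S_rare / C_ace + (F1 / C_ace) * gamma^2`, where
#' `C_ace = 1 - F1 / N_rare` is the rare-class sample coverage and `gamma^2`
#' the rare-class coefficient of variation, floored at 0. When every rare
#' taxon is a singleton (`C_ace = 0`) the estimator is undefined and the
#' function falls back to [chao1()].
#'
#' @param x counts for one sample.
#' @param rare_cutoff taxa with counts `<= rare_cutoff` form the rare class.
#' @return estimated richness.
#' @export
ace <- function(x, rare_cutoff = 10) {
  x <- x[x > 0]
  if (!length(x)) stopf("sample has no reads")
  rare <- x[x <= rare_cutoff]
  s_abund <- sum(x > rare_cutoff)
  s_rare <- length(rare)
  if (s_rare == 0) return(as.numeric(s_abund))
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) return(chao1(x))
  i <- seq_len(rare_cutoff)
  fi <- vapply(i, function(k) sum(rare == k), numeric(1L))
  gamma2 <- max((s_rare / c_ace) * sum(i * (i - 1) * fi) /
                  (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + (f1 / c_ace) * gamma2
}

#' Shannon diversity
#'
#' `H = -sum p_i log(p_i)` with `0 log 0 := 0`; base 2 (bits) by default.
#'
#' @param x counts for one sample.
#' @param base logarithm base.
#' @return Shannon index, `>= 0`.
#' @export
shannon <- function(x, base = 2) {
  x <- x[x > 0]
  if (!length(x)) stopf("sample has no reads")
  p <- x / sum(x)
  -sum(p * log(p, base = base))
}

#' Gini-Simpson diversity
#'
#' `1 - sum p_i^2`: the probability that two random reads are different taxa.
#'
#' @param x counts for one sample.
#' @return value in `[0, 1]`.
#' @export
simpson <- function(x) {
  x <- x[x > 0]
  if (!length(x)) stopf("sample has no reads")
  p <- x / sum(x)
  1 - sum(p^2)
}

#' Alpha-diversity table for every sample
#'
#' One row per sample with reads, observed OTUs, Good's coverage, Chao1,
#' ACE, Shannon (bits) and Gini-Simpson — the layout of a standard
#' richness-and-diversity report.
#'
#' @param counts count matrix (samples x taxa).
#' @param rarefy optional even depth to subsample every sample to (without
#'   replacement) before estimating; default `NULL` uses the raw counts.
#' @param seed RNG seed for rarefaction.
#' @param shannon_base logarithm base for Shannon.
#' @return data frame, one row per sample.
#' @export
alpha_diversity <- function(counts, rarefy = NULL, seed = 1L,
                            shannon_base = 2) {
  counts <- validate_counts(counts)
  if (!is.null(rarefy)) {
    if (any(rowSums(counts) < rarefy))
      stopf("rarefaction depth %d exceeds the smallest library", rarefy)
    set.seed(stage_seed(seed, "rarefy"))
    counts <- vegan::rrarefy(counts, rarefy)
  }
  data.frame(
    sample_id = rownames(counts),
    reads = as.integer(rowSums(counts)),
    observed_otus = as.integer(rowSums(counts > 0)),
    coverage = apply(counts, 1L, goods_coverage),
    chao1 = apply(counts, 1L, chao1),
    ace = apply(counts, 1L, ace),
    shannon = apply(counts, 1L, shannon, base = shannon_base),
    simpson = apply(counts, 1L, simpson),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Group mean and standard deviation of alpha diversity
#'
#' @param alpha data frame from [alpha_diversity()].
#' @param groups named character vector (`sample_id -> group`).
#' @return data frame: one row per group, `mean` and `sd` per index.
#' @export
alpha_group_summary <- function(alpha, groups) {
  g <- groups[alpha$sample_id]
  if (anyNA(g)) stopf("sample(s) missing from metadata: %s",
                      paste(alpha$sample_id[is.na(g)], collapse = ", "))
  num <- alpha[, setdiff(names(alpha), "sample_id"), drop = FALSE]
  out <- do.call(rbind, lapply(split(num, g), function(d) {
    m <- colMeans(d); s <- apply(d, 2L, stats::sd)
    stats::setNames(as.data.frame(as.list(c(m, s))),
                    c(paste0(names(m), "_mean"), paste0(names(s), "_sd")))
  }))
  data.frame(group = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = 1 - 2 sum min(x_i, y_i) / (sum x + sum y)`, on raw counts.
#'
#' @param counts count matrix (samples x taxa), >= 2 samples.
#' @return a [stats::dist] with sample labels, values in `[0, 1]`.
#' @export
bray_curtis <- function(counts) {
  counts <- validate_counts(counts)
  if (nrow(counts) < 2L) stopf("need at least 2 samples")
  vegan::vegdist(counts, method = "bray")
}

#' @keywords internal
#' @noRd
edge_tip_incidence <- function(tree) {
  # logical n_edge x n_tip matrix: tips descending from each edge
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  below <- matrix(FALSE, n_node, n_tip)
  below[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  tr <- stats::reorder(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    below[tr$edge[k, 1L], ] <- below[tr$edge[k, 1L], ] | below[tr$edge[k, 2L], ]
  }
  inc <- below[tree$edge[, 2L], , drop = FALSE]
  colnames(inc) <- tree$tip.label
  inc
}

#' Unweighted UniFrac distance
#'
#' For each sample pair: the branch length leading only to tips present in
#' exactly one of the two samples, divided by the branch length leading to
#' tips present in either. Presence is `count > 0`.
#'
#' @param counts count matrix (samples x taxa); every taxon with a nonzero
#'   count must be a tip of `tree`.
#' @param tree [ape::phylo] phylogeny with branch lengths.
#' @return a [stats::dist] with sample labels, values in `[0, 1]`.
#' @export
unweighted_unifrac <- function(counts, tree) {
  counts <- validate_counts(counts)
  present_taxa <- colnames(counts)[colSums(counts) > 0]
  miss <- setdiff(present_taxa, tree$tip.label)
  if (length(miss))
    stopf("taxa missing from tree: %s", paste(utils::head(miss, 3L), collapse = ", "))
  validate_phylogeny(tree)
  inc <- edge_tip_incidence(tree)
  pres <- t(counts > 0)                       # taxa x samples
  pres <- pres[match(colnames(inc), rownames(pres)), , drop = FALSE]
  pres[is.na(pres)] <- FALSE                  # tree tips absent from table
  edge_in <- (inc %*% pres) > 0               # edges x samples
  len <- tree$edge.length
  n <- nrow(counts)
  d <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- edge_in[, i]; b <- edge_in[, j]
      union_len <- sum(len[a | b])
      d[i, j] <- d[j, i] <- if (union_len == 0) 0 else sum(len[xor(a, b)]) / union_len
    }
  }
  stats::as.dist(d)
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-d^2 / 2` followed by eigendecomposition
#' (classical MDS, [stats::cmdscale]); coordinates are scaled by the square
#' root of the eigenvalues. Negative eigenvalues are excluded from the
#' variance proportions and reported in `$negative_eig`.
#'
#' @param d a [stats::dist] or symmetric matrix, `n >= 3`.
#' @param k number of axes to return.
#' @return object of class `"pcoa_ordination"`: `points` (n x k),
#'   `eigenvalues`, `proportion` (per returned axis), `negative_eig`.
#' @export
pcoa <- function(d, k = 2L) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n < 3L) stopf("PCoA needs at least 3 samples")
  k <- min(k, n - 1L)
  res <- stats::cmdscale(d, k = k, eig = TRUE)
  eig <- res$eig
  pos <- eig[eig > sqrt(.Machine$double.eps) * max(abs(eig))]
  prop <- if (length(pos)) eig[seq_len(k)] / sum(pos) else rep(0, k)
  prop <- pmax(prop, 0)
  pts <- res$points
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  structure(list(points = pts, eigenvalues = eig,
                 proportion = prop[seq_len(ncol(pts))],
                 negative_eig = eig[eig < 0]),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat(sprintf("PCoA ordination: %d samples, %d axes\n", nrow(x$points),
              ncol(x$points)))
  cat(sprintf("  variance explained: %s\n",
              paste(sprintf("%.1f%%", 100 * x$proportion), collapse = ", ")))
  if (length(x$negative_eig))
    cat(sprintf("  %d negative eigenvalue(s), min %.3g\n",
                length(x$negative_eig), min(x$negative_eig)))
  invisible(x)
}
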