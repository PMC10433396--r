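# Phylogenetic null-model inference of community assembly processes.
#
# The chain is: abundance-weighted (beta) mean nearest taxon distances ->
# standardized effect sizes against a tip-shuffling null (ses.MNTD within a
# sample, beta-NTI between samples) -> Bray-Curtis-based Raup-Crick metric
# for the pairs the phylogenetic test leaves unresolved -> a five-way
# process classification:
#
#   beta-NTI >  2                      variable selection      (deterministic)
#   beta-NTI < -2                      homogeneous selection   (deterministic)
#   |beta-NTI| <= 2, RC_bray >  0.95   dispersal limitation    (stochastic)
#   |beta-NTI| <= 2, RC_bray < -0.95   homogenizing dispersal  (stochastic)
#   |beta-NTI| <= 2, |RC_bray| <= 0.95 drift                   (stochastic)
#
# The null scheme is tip-label shuffling over the full tree (the
# "taxa.labels" convention): each null draw permutes the rows/columns of the
# patristic distance matrix, preserving every sample's richness and
# abundances by construction. Within a draw the same shuffle is applied to
# the whole tree, so both samples of a pair see one relabelling; identical
# communities therefore give a degenerate null (sd = 0) which is flagged NA,
# never silently zero.

PROCESS_LEVELS <- c("variable_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal", "drift")

#' @keywords internal
#' @noRd
patristic_matrix <- function(tree, taxa) {
  d <- stats::cophenetic(tree)
  miss <- setdiff(taxa, rownames(d))
  if (length(miss))
    stopf("taxa missing from tree: %s", paste(utils::head(miss, 3L), collapse = ", "))
  d[taxa, taxa, drop = FALSE]
}

#' Mean nearest taxon distance of one community
#'
#' `sum_i f_i * min_{j != i, j present} d(i, j)`: the abundance-weighted
#' mean patristic distance from each taxon to its closest relative in the
#' same community. With `abundance_weighted = FALSE` each present taxon
#' weighs `1/S`.
#'
#' @param x counts (or abundances) for one sample, named by taxon.
#' @param tree [ape::phylo], or a precomputed patristic distance matrix.
#' @param abundance_weighted weight taxa by relative abundance (default).
#' @return MNTD in branch-length units.
#' @export
mntd <- function(x, tree, abundance_weighted = TRUE) {
  present <- names(x)[x > 0]
  if (length(present) < 2L) stopf("MNTD needs at least 2 taxa present")
  d <- if (is.matrix(tree)) tree[present, present, drop = FALSE]
       else patristic_matrix(tree, present)
  diag(d) <- Inf
  nnd <- row_mins(d)
  f <- if (abundance_weighted) x[present] / sum(x[present])
       else rep(1 / length(present), length(present))
  sum(f * nnd)
}

#' Between-community mean nearest taxon distance (beta-MNTD)
#'
#' For samples k and m:
#' `0.5 * ( sum_{i in k} f_ik min_{j in m} d(i,j) +
#'          sum_{j in m} f_jm min_{i in k} d(i,j) )`.
#' A taxon present in both communities is its own nearest neighbour
#' (distance 0), so identical communities have beta-MNTD 0.
#'
#' @param counts count matrix (samples x taxa); no empty sample.
#' @param tree [ape::phylo] over the taxa.
#' @param abundance_weighted weight by relative abundance (default).
#' @return a [stats::dist] of beta-MNTD values.
#' @export
beta_mntd <- function(counts, tree, abundance_weighted = TRUE) {
  counts <- validate_counts(counts)
  d <- patristic_matrix(tree, colnames(counts))
  stats::as.dist(beta_mntd_matrix(counts, d, abundance_weighted))
}

#' @keywords internal
#' @noRd
beta_mntd_matrix <- function(counts, d, abundance_weighted = TRUE) {
  # d: patristic matrix in column order of counts
  n <- nrow(counts)
  p <- ncol(counts)
  f <- if (abundance_weighted) rel_abundance(counts)
       else rel_abundance((counts > 0) * 1L)
  # nnd[i, m] = min over taxa j present in sample m of d[i, j]
  nnd <- matrix(0, p, n)
  for (m in seq_len(n)) {
    idx <- which(counts[m, ] > 0)
    nnd[, m] <- row_mins(d[, idx, drop = FALSE])
  }
  half <- f %*% nnd                 # half[k, m] = sum_i f_ik nnd_i(m)
  bm <- 0.5 * (half + t(half))
  diag(bm) <- 0
  dimnames(bm) <- list(rownames(counts), rownames(counts))
  bm
}

#' Standardized effect size of MNTD (ses.MNTD)
#'
#' Null model: shuffle taxon labels across all tree tips (`taxa.labels`
#' scheme), recompute MNTD per draw; `ses = (obs - mean_null) / sd_null`.
#' `NTI = -ses`. When the null is degenerate (`sd_null = 0`) the effect size
#' is flagged `NA` rather than reported as 0.
#'
#' @param counts count matrix (samples x taxa).
#' @param tree [ape::phylo] over the taxa.
#' @param n_null number of null draws (>= 99; default 999).
#' @param seed RNG seed.
#' @param abundance_weighted weight by relative abundance (default).
#' @return data frame: `sample_id`, `mntd_obs`, `null_mean`, `null_sd`,
#'   `ses_mntd`, `nti`.
#' @export
ses_mntd <- function(counts, tree, n_null = 999L, seed = 1L,
                     abundance_weighted = TRUE) {
  counts <- validate_counts(counts)
  if (n_null < 99L) stopf("n_null must be >= 99")
  # canonical taxon order so null draws do not depend on input column order
  counts <- counts[, order(colnames(counts)), drop = FALSE]
  d <- patristic_matrix(tree, colnames(counts))
  p <- ncol(counts)
  obs <- apply(counts, 1L, mntd, tree = d,
               abundance_weighted = abundance_weighted)
  set.seed(seed)
  nulls <- matrix(0, n_null, nrow(counts))
  for (b in seq_len(n_null)) {
    perm <- sample.int(p)
    dp <- d[perm, perm]
    dimnames(dp) <- dimnames(d)
    nulls[b, ] <- apply(counts, 1L, mntd, tree = dp,
                        abundance_weighted = abundance_weighted)
  }
  mu <- colMeans(nulls)
  sdev <- apply(nulls, 2L, stats::sd)
  ses <- ifelse(sdev > 0, (obs - mu) / sdev, NA_real_)
  if (anyNA(ses))
    warning("degenerate null (sd = 0) for sample(s): ",
            paste(rownames(counts)[is.na(ses)], collapse = ", "), call. = FALSE)
  data.frame(sample_id = rownames(counts), mntd_obs = obs, null_mean = mu,
             null_sd = sdev, ses_mntd = ses, nti = -ses,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Beta nearest taxon index (beta-NTI)
#'
#' Standardized effect size of beta-MNTD under tip-label shuffling: per null
#' draw one shuffle of the whole tree is shared by both communities of every
#' pair; `beta-NTI = (obs - mean_null) / sd_null`. Values above 2 indicate
#' more phylogenetic turnover than expected (variable selection), below -2
#' less than expected (homogeneous selection).
#'
#' @inheritParams ses_mntd
#' @return list of class `"beta_nti"`: `beta_nti` (dist, `NA` where the null
#'   is degenerate), `beta_mntd_obs` (dist), `null_mean`, `null_sd` (dist),
#'   `n_null`.
#' @export
beta_nti <- function(counts, tree, n_null = 999L, seed = 1L,
                     abundance_weighted = TRUE) {
  counts <- validate_counts(counts)
  if (n_null < 99L) stopf("n_null must be >= 99")
  if (nrow(counts) < 2L) stopf("need at least 2 samples")
  # canonical taxon order so null draws do not depend on input column order
  counts <- counts[, order(colnames(counts)), drop = FALSE]
  d <- patristic_matrix(tree, colnames(counts))
  obs <- beta_mntd_matrix(counts, d, abundance_weighted)
  p <- ncol(counts)
  set.seed(seed)
  s1 <- matrix(0, nrow(counts), nrow(counts))
  s2 <- matrix(0, nrow(counts), nrow(counts))
  for (b in seq_len(n_null)) {
    perm <- sample.int(p)
    bm <- beta_mntd_matrix(counts, d[perm, perm], abundance_weighted)
    s1 <- s1 + bm
    s2 <- s2 + bm * bm
  }
  mu <- s1 / n_null
  va <- pmax((s2 - n_null * mu * mu) / (n_null - 1), 0)
  sdev <- sqrt(va)
  bnti <- ifelse(sdev > 0, (obs - mu) / sdev, NA_real_)
  diag(bnti) <- 0
  dimnames(bnti) <- dimnames(mu) <- dimnames(sdev) <- dimnames(obs)
  und <- which(is.na(as.matrix(stats::as.dist(bnti))), arr.ind = TRUE)
  if (nrow(und))
    warning("beta-NTI undefined (degenerate null) for ",
            nrow(und) / 2L, " sample pair(s)", call. = FALSE)
  structure(list(beta_nti = stats::as.dist(bnti),
                 beta_mntd_obs = stats::as.dist(obs),
                 null_mean = stats::as.dist(mu),
                 null_sd = stats::as.dist(sdev),
                 n_null = n_null),
            class = "beta_nti")
}

#' @keywords internal
#' @noRd
rc_null_community <- function(richness, reads, occupancy, pool_ab) {
  # one richness- and reads-preserving null assemblage (Raup-Crick null):
  # draw `richness` taxa without replacement with prob ~ occupancy (each
  # gets one read), then allot the remaining reads with prob ~ pool
  # relative abundance among the drawn taxa.
  p <- length(occupancy)
  chosen <- if (richness >= p) seq_len(p)
            else sample.int(p, richness, prob = occupancy)
  x <- integer(p)
  x[chosen] <- 1L
  extra <- reads - richness
  if (extra > 0L)
    x[chosen] <- x[chosen] + as.integer(stats::rmultinom(1L, extra, pool_ab[chosen]))
  x
}

#' Bray-Curtis-based Raup-Crick metric (RC_bray)
#'
#' For each sample pair, the observed Bray-Curtis dissimilarity is ranked
#' within a null distribution of dissimilarities between random assemblages
#' that preserve each sample's observed richness and total reads: taxa are
#' drawn without replacement with probability proportional to occupancy
#' (the fraction of samples containing the taxon), then reads are allotted
#' to the drawn taxa with probability proportional to metacommunity relative
#' abundance. `RC = 2 * ( (#null < obs + 0.5 #ties) / n_null - 0.5 )`, in
#' `[-1, 1]`; ties (equality to within 1e-12) take half weight.
#'
#' @param counts count matrix (samples x taxa), >= 2 taxa in the
#'   metacommunity.
#' @param n_null number of null draws (>= 99; default 999).
#' @param seed RNG seed.
#' @return a [stats::dist] of RC_bray values.
#' @export
rc_bray <- function(counts, n_null = 999L, seed = 1L) {
  counts <- validate_counts(counts)
  if (n_null < 99L) stopf("n_null must be >= 99")
  # canonical sample and taxon order so the null stream is order-invariant
  orig <- rownames(counts)
  counts <- counts[order(rownames(counts)), order(colnames(counts)),
                   drop = FALSE]
  occ <- colSums(counts > 0)
  if (sum(occ > 0) < 2L) stopf("RC_bray needs at least 2 taxa in the metacommunity")
  pool_ab <- colSums(counts) / sum(counts)
  rich <- rowSums(counts > 0)
  reads <- rowSums(counts)
  n <- nrow(counts)
  obs <- as.matrix(vegan::vegdist(counts, "bray"))
  less <- matrix(0, n, n)
  ties <- matrix(0, n, n)
  set.seed(seed)
  for (b in seq_len(n_null)) {
    nullc <- t(vapply(seq_len(n),
                      function(s) rc_null_community(rich[s], reads[s], occ, pool_ab),
                      integer(ncol(counts))))
    bc <- as.matrix(vegan::vegdist(nullc, "bray"))
    less <- less + (bc < obs - 1e-12)
    ties <- ties + (abs(bc - obs) <= 1e-12)
  }
  rc <- 2 * ((less + 0.5 * ties) / n_null - 0.5)
  diag(rc) <- 0
  dimnames(rc) <- list(rownames(counts), rownames(counts))
  stats::as.dist(rc[orig, orig])
}

#' Classify assembly processes from beta-NTI and RC_bray
#'
#' Deterministic processes first: `beta-NTI > 2` is variable selection,
#' `beta-NTI < -2` homogeneous selection. Pairs with `|beta-NTI| <= 2` are
#' resolved by RC_bray: `> 0.95` dispersal limitation, `< -0.95`
#' homogenizing dispersal, otherwise drift. Pairs with an undefined
#' beta-NTI get `NA` (excluded, counted by the caller).
#'
#' @param beta_nti numeric vector (or dist) of beta-NTI values.
#' @param rc_bray numeric vector (or dist) of RC_bray values, same length.
#' @return factor with levels `variable_selection`, `homogeneous_selection`,
#'   `dispersal_limitation`, `homogenizing_dispersal`, `drift`.
#' @export
classify_assembly <- function(beta_nti, rc_bray) {
  b <- as.numeric(if (inherits(beta_nti, "dist")) beta_nti else beta_nti)
  r <- as.numeric(if (inherits(rc_bray, "dist")) rc_bray else rc_bray)
  if (length(b) != length(r)) stopf("beta_nti and rc_bray lengths differ")
  lab <- ifelse(is.na(b), NA_character_,
         ifelse(b > 2, "variable_selection",
         ifelse(b < -2, "homogeneous_selection",
         ifelse(is.na(r), NA_character_,
         ifelse(r > 0.95, "dispersal_limitation",
         ifelse(r < -0.95, "homogenizing_dispersal", "drift"))))))
  factor(lab, levels = PROCESS_LEVELS)
}

#' Summarize assembly-process fractions
#'
#' Fractions of classified pairs per process, plus the deterministic
#' (variable + homogeneous selection) and stochastic (the other three)
#' totals. Scope is either all pairs (`"overall"`) or within-group pairs
#' tallied per group (`"within_group"`).
#'
#' @param labels factor from [classify_assembly()], one per sample pair.
#' @param groups optional named group vector; required for
#'   `scope = "within_group"` and for the pair `group_context`.
#' @param pairs optional data frame with columns `sample_i`, `sample_j`
#'   matching `labels`; required when `groups` is given.
#' @param scope `"overall"` or `"within_group"`.
#' @return data frame: one row per scope unit with counts and fractions per
#'   process, `deterministic_fraction`, `stochastic_fraction`,
#'   `n_excluded` (pairs with undefined statistics).
#' @export
summarize_processes <- function(labels, groups = NULL, pairs = NULL,
                                scope = c("overall", "within_group")) {
  scope <- match.arg(scope)
  tally <- function(lab, unit) {
    lab_ok <- lab[!is.na(lab)]
    if (!length(lab_ok)) stopf("no classified pairs in scope '%s'", unit)
    counts <- table(factor(lab_ok, levels = PROCESS_LEVELS))
    fr <- as.numeric(counts) / length(lab_ok)
    det <- sum(fr[1:2])
    out <- data.frame(scope = unit, n_pairs = length(lab_ok),
                      n_excluded = sum(is.na(lab)),
                      stringsAsFactors = FALSE)
    for (k in seq_along(PROCESS_LEVELS)) {
      out[[paste0("n_", PROCESS_LEVELS[k])]] <- as.integer(counts[k])
      out[[paste0("frac_", PROCESS_LEVELS[k])]] <- fr[k]
    }
    out$deterministic_fraction <- det
    out$stochastic_fraction <- 1 - det
    out
  }
  if (scope == "overall") return(tally(labels, "overall"))
  if (is.null(groups) || is.null(pairs))
    stopf("within_group scope needs `groups` and `pairs`")
  gi <- groups[pairs$sample_i]
  gj <- groups[pairs$sample_j]
  within <- !is.na(gi) & gi == gj
  if (!any(within)) stopf("no within-group pairs in scope")
  do.call(rbind, lapply(sort(unique(gi[within])), function(g) {
    tally(labels[within & gi == g], g)
  }))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper triangles, with significance from
#' jointly permuting the rows and columns of the second matrix
#' (`p = (1 + #{perm r >= obs r}) / (1 + n_perm)`). Thin seeded wrapper
#' around [vegan::mantel()].
#'
#' @param dm1,dm2 [stats::dist] objects (or symmetric matrices) over the
#'   same ids, `n >= 4`.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @param method correlation method (default `"pearson"`).
#' @return list: `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(dm1, dm2, n_perm = 999L, seed = 1L,
                        method = "pearson") {
  dm1 <- stats::as.dist(dm1)
  dm2 <- stats::as.dist(dm2)
  if (attr(dm1, "Size") < 4L) stopf("Mantel test needs at least 4 samples")
  l1 <- attr(dm1, "Labels"); l2 <- attr(dm2, "Labels")
  if (!is.null(l1) && !is.null(l2)) {
    if (!setequal(l1, l2)) stopf("distance matrices have different ids")
    if (!identical(l1, l2)) {
      m2 <- dist_to_matrix(dm2)
      dm2 <- stats::as.dist(m2[l1, l1])
    }
  }
  set.seed(seed)
  res <- vegan::mantel(dm1, dm2, method = method, permutations = n_perm)
  list(r = unname(res$statistic), p = unname(res$signif), n_perm = n_perm)
}

#' Euclidean distance on z-scored environmental variables
#'
#' Companion for [mantel_test()]: variables are standardized to mean 0 and
#' sd 1 before the Euclidean distance, since environmental parameters come
#' in incommensurable units.
#'
#' @param env data frame or matrix of numeric variables, samples in rows.
#' @return a [stats::dist].
#' @export
env_distance <- function(env) {
  m <- scale(as.matrix(env))
  m[, colSums(!is.finite(m)) > 0] <- 0  # constant variables carry no signal
  stats::dist(m)
}

#' Full community-assembly inference for a dataset
#'
#' Runs [ses_mntd()], [beta_nti()], [rc_bray()] and [classify_assembly()]
#' and assembles the per-pair table and process summaries.
#'
#' @param counts count matrix (samples x taxa).
#' @param tree [ape::phylo] over the taxa.
#' @param groups optional named group vector (`sample_id -> group`).
#' @param n_null null draws for both null models (default 999).
#' @param seed global seed; per-stage seeds are derived with fixed offsets.
#' @param abundance_weighted weight beta-MNTD by relative abundance.
#' @param prune drop count-table taxa absent from the tree (default: error).
#' @return object of class `"community_assembly"` with elements `pairs`
#'   (per-pair table), `ses_mntd`, `summary_overall`, `summary_within`
#'   (when groups given), `n_null`, `seed`.
#' @export
community_assembly <- function(counts, tree, groups = NULL, n_null = 999L,
                               seed = 1L, abundance_weighted = TRUE,
                               prune = FALSE) {
  counts <- validate_counts(counts)
  counts <- match_tree_taxa(counts, tree, prune = prune)
  if (!is.null(groups)) groups <- match_sample_groups(counts, groups)
  ses <- ses_mntd(counts, tree, n_null = n_null,
                  seed = stage_seed(seed, "assembly"),
                  abundance_weighted = abundance_weighted)
  bn <- beta_nti(counts, tree, n_null = n_null,
                 seed = stage_seed(seed, "assembly"),
                 abundance_weighted = abundance_weighted)
  rc <- rc_bray(counts, n_null = n_null, seed = stage_seed(seed, "rcbray"))
  pairs <- upper_pairs(rownames(counts))
  pairs$beta_mntd_obs <- as.numeric(bn$beta_mntd_obs)
  pairs$beta_nti <- as.numeric(bn$beta_nti)
  pairs$rc_bray <- as.numeric(rc)
  pairs$process <- classify_assembly(pairs$beta_nti, pairs$rc_bray)
  pairs$group_context <- if (is.null(groups)) NA_character_ else {
    gi <- groups[pairs$sample_i]; gj <- groups[pairs$sample_j]
    ifelse(gi == gj, gi, "between")
  }
  out <- list(pairs = pairs, ses_mntd = ses,
              summary_overall = summarize_processes(pairs$process),
              summary_within = if (!is.null(groups))
                summarize_processes(pairs$process, groups, pairs,
                                    scope = "within_group"),
              n_null = n_null, seed = seed, groups = groups)
  class(out) <- "community_assembly"
  out
}

#' @export
print.community_assembly <- function(x, ...) {
  s <- x$summary_overall
  cat(sprintf("Community assembly inference: %d sample pairs, %d null draws\n",
              s$n_pairs, x$n_null))
  cat(sprintf("  deterministic %.2f%% (variable %.2f%%, homogeneous %.2f%%)\n",
              100 * s$deterministic_fraction, 100 * s$frac_variable_selection,
              100 * s$frac_homogeneous_selection))
  cat(sprintf("  stochastic    %.2f%% (dispersal lim. %.2f%%, homog. dispersal %.2f%%, drift %.2f%%)\n",
              100 * s$stochastic_fraction, 100 * s$frac_dispersal_limitation,
              100 * s$frac_homogenizing_dispersal, 100 * s$frac_drift))
  if (s$n_excluded > 0)
    cat(sprintf("  %d pair(s) excluded (undefined beta-NTI)\n", s$n_excluded))
  invisible(x)
}

#' @export
summary.community_assembly <- function(object, ...) {
  print(object)
  if (!is.null(object$summary_within)) {
    cat("\nWithin-group process fractions:\n")
    w <- object$summary_within
    print(w[, c("scope", "n_pairs", "frac_homogeneous_selection",
                "frac_dispersal_limitation", "frac_drift",
                "deterministic_fraction")], row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' @export
plot.community_assembly <- function(x, ...) {
  ctx <- x$pairs$group_context
  if (all(is.na(ctx))) ctx <- rep("all pairs", nrow(x$pairs))
  graphics::boxplot(beta_nti ~ factor(ctx), data = x$pairs,
                    ylab = expression(beta * "NTI"), xlab = "",
                    las = 2, ...)
  graphics::abline(h = c(-2, 2), lty = 2, col = "blue")
  invisible(x)
}
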