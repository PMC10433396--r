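# Readers and writers for the plain-text formats the pipeline touches:
# OTU count tables (TSV), rooted phylogenies (Newick), sample metadata (TSV),
# SIF edge lists and GraphML networks, and generic TSV result tables.
#
# Count tables are held as plain integer matrices, samples in rows and taxa
# in columns, with unique dimnames — the convention vegan and picante use.
# All validation is strict: malformed input raises an error naming the
# offending row/column; nothing is silently coerced.

#' Validate a sample-by-taxon count matrix
#'
#' Checks the invariants every downstream analysis relies on: a numeric
#' matrix of non-negative integers with unique sample and taxon ids and no
#' all-zero sample.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns, with
#'   dimnames.
#' @return the validated matrix, invisibly storage-mode integer.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stopf("counts must be a numeric matrix (samples x taxa)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must have sample ids as rownames and taxon ids as colnames")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup)) stopf("duplicate sample id(s): %s", paste(unique(dup), collapse = ", "))
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup)) stopf("duplicate taxon id(s): %s", paste(unique(dup), collapse = ", "))
  if (anyNA(counts)) stopf("counts contain missing values")
  if (any(counts < 0)) {
    w <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stopf("negative count at sample '%s', taxon '%s'",
          rownames(counts)[w[1L]], colnames(counts)[w[2L]])
  }
  if (any(counts != round(counts))) {
    w <- which(counts != round(counts), arr.ind = TRUE)[1L, ]
    stopf("non-integer count at sample '%s', taxon '%s'",
          rownames(counts)[w[1L]], colnames(counts)[w[2L]])
  }
  zero <- rowSums(counts) == 0
  if (any(zero))
    stopf("all-zero sample(s): %s", paste(rownames(counts)[zero], collapse = ", "))
  storage.mode(counts) <- "integer"
  counts
}

#' Read an OTU count table from TSV
#'
#' Expects one header row and one id column (a leading `"#OTU ID"` header is
#' tolerated). By default rows are taxa (the usual OTU-table layout); the
#' returned matrix is always normalized to samples x taxa.
#'
#' @param path path to a tab-separated count table.
#' @param orientation `"taxa_as_rows"` (default) or `"samples_as_rows"`.
#' @return integer matrix, samples in rows, taxa in columns.
#' @export
read_count_table <- function(path,
                             orientation = c("taxa_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("count table not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("count table %s needs an id column plus data", path)
  ids <- as.character(df[[1L]])
  dat <- df[, -1L, drop = FALSE]
  bad <- !vapply(dat, is.numeric, logical(1L))
  if (any(bad))
    stopf("non-numeric cell(s) in column '%s' of %s", names(dat)[bad][1L], path)
  m <- as.matrix(dat)
  rownames(m) <- ids
  if (orientation == "taxa_as_rows") m <- t(m)
  validate_counts(m)
}

#' Write an OTU count table to TSV
#'
#' @param counts validated count matrix (samples x taxa).
#' @param path output path.
#' @param orientation layout to write; `"taxa_as_rows"` (default) writes the
#'   conventional OTU table with a `"#OTU ID"` id column.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path,
                              orientation = c("taxa_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  counts <- validate_counts(counts)
  if (orientation == "taxa_as_rows") {
    out <- data.frame(id = colnames(counts), t(counts), check.names = FALSE,
                      stringsAsFactors = FALSE)
    names(out)[1L] <- "#OTU ID"
  } else {
    out <- data.frame(sample_id = rownames(counts), counts, check.names = FALSE,
                      stringsAsFactors = FALSE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from a Newick file
#'
#' The tree must carry a branch length on every edge (the null models need
#' patristic distances) and all lengths must be non-negative.
#'
#' @param path path to a single-tree Newick file.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stopf("tree file not found: %s", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  for (k in seq_len(nchar(txt))) {
    ch <- substr(txt, k, k)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth < 0L)
      stopf("unbalanced ')' in Newick string at character offset %d", k)
  }
  if (depth != 0L)
    stopf("unbalanced '(' in Newick string (%d unclosed at end)", depth)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stopf("cannot parse Newick in %s: %s",
                                             path, conditionMessage(e)))
  if (is.null(tree)) stopf("cannot parse Newick in %s", path)
  validate_phylogeny(tree)
}

#' Validate a phylogeny for null-model use
#'
#' @param tree an [ape::phylo] object.
#' @return the tree, invisibly unchanged.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length))
    stopf("tree has no branch lengths; patristic distances are undefined")
  if (length(tree$edge.length) != nrow(tree$edge))
    stopf("tree is missing branch lengths on %d edge(s)",
          nrow(tree$edge) - length(tree$edge.length))
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stopf("tree has missing or negative branch lengths")
  if (anyDuplicated(tree$tip.label))
    stopf("duplicate tip label(s): %s",
          paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  tree
}

#' Write a phylogeny to a Newick file
#'
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read sample metadata mapping samples to treatment groups
#'
#' @param path TSV with columns `sample_id` and `group`.
#' @return named character vector: `sample_id -> group`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stopf("metadata file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("metadata is missing column(s): %s", paste(miss, collapse = ", "))
  ids <- as.character(df$sample_id)
  if (anyDuplicated(ids))
    stopf("duplicate sample id(s) in metadata: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(as.character(df$group), ids)
}

#' Write sample metadata
#'
#' @param groups named character vector (`sample_id -> group`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(groups, path) {
  utils::write.table(
    data.frame(sample_id = names(groups), group = unname(groups)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check sample groups against a count matrix
#'
#' Every sample in the count matrix must be assigned to exactly one group,
#' and within-group pairwise statistics need at least two samples per group.
#'
#' @param counts count matrix (samples x taxa).
#' @param groups named character vector from [read_metadata()].
#' @return the groups restricted and reordered to the samples of `counts`.
#' @export
match_sample_groups <- function(counts, groups) {
  miss <- setdiff(rownames(counts), names(groups))
  if (length(miss))
    stopf("sample(s) in counts missing from metadata: %s", paste(miss, collapse = ", "))
  g <- groups[rownames(counts)]
  small <- names(which(table(g) < 2L))
  if (length(small))
    warning(sprintf("group(s) with fewer than 2 samples: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
  g
}

#' Align a count matrix with a phylogeny
#'
#' Taxa present in the counts but absent from the tree are a hard error by
#' default: silently dropping them changes every phylogenetic statistic.
#' With `prune = TRUE` those taxa are removed from the counts (and extra tree
#' tips are always ignored by downstream code).
#'
#' @param counts count matrix (samples x taxa).
#' @param tree [ape::phylo] phylogeny over the taxa.
#' @param prune drop count-table taxa missing from the tree instead of
#'   erroring.
#' @return the (possibly pruned) count matrix.
#' @export
match_tree_taxa <- function(counts, tree, prune = FALSE) {
  miss <- setdiff(colnames(counts), tree$tip.label)
  if (!length(miss)) return(counts)
  if (!prune)
    stopf("%d taxa in counts are not tips of the tree (e.g. %s); use prune = TRUE to drop them",
          length(miss), paste(utils::head(miss, 3L), collapse = ", "))
  keep <- setdiff(colnames(counts), miss)
  validate_counts(counts[, keep, drop = FALSE])
}

#' Write a network edge list in SIF format
#'
#' One row per edge: `taxonA <sign> taxonB`, sign `pos` or `neg`.
#'
#' @param edges data frame with columns `taxon_a`, `taxon_b`, `sign`
#'   (`"positive"`/`"negative"` or `"pos"`/`"neg"`). May be empty.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  if (is.null(edges) || nrow(edges) == 0L) {
    writeLines(character(0L), path)
    return(invisible(path))
  }
  sgn <- substr(as.character(edges$sign), 1L, 3L)
  if (!all(sgn %in% c("pos", "neg")))
    stopf("edge sign must be positive or negative")
  writeLines(paste(edges$taxon_a, sgn, edges$taxon_b), path)
  invisible(path)
}

#' Write a network in GraphML format
#'
#' @param graph an [igraph::igraph] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Write any tabular result as TSV
#'
#' Tab-separated, UTF-8, `.` decimal, no quoting; columns in the order given.
#'
#' @param x data frame or matrix.
#' @param path output path.
#' @param row_names include row names as a leading `id` column.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, row_names = FALSE) {
  if (row_names) {
    x <- data.frame(id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
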