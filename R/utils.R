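# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
row_mins <- function(m) {
  # fast row-wise minima; max.col is C-level, matrices here are small-ish
  if (!is.matrix(m)) m <- as.matrix(m)
  if (ncol(m) == 1L) return(as.vector(m))
  idx <- max.col(-m, ties.method = "first")
  m[cbind(seq_len(nrow(m)), idx)]
}

#' @keywords internal
#' @noRd
rel_abundance <- function(counts) {
  sweep(counts, 1L, rowSums(counts), "/")
}

#' Derive a stage seed from a global seed
#'
#' Stage seeds are the global seed plus a fixed per-stage offset, folded into
#' the 32-bit integer range, so any stage can be re-run in isolation and still
#' reproduce the full-pipeline result.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed for the stage.
#' @export
stage_seed <- function(seed, stage = c("tree", "trait", "pool", "sampling",
                                       "assembly", "rcbray", "network",
                                       "modules", "rarefy")) {
  stage <- match.arg(stage)
  offsets <- c(tree = 1000L, trait = 2000L, pool = 3000L, sampling = 4000L,
               assembly = 5000L, rcbray = 6000L, network = 7000L,
               modules = 8000L, rarefy = 9000L)
  as.integer((as.numeric(seed) + offsets[[stage]]) %% 2147483647)
}

#' @keywords internal
#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @keywords internal
#' @noRd
dist_to_matrix <- function(d) {
  m <- as.matrix(d)
  if (is.null(rownames(m))) {
    ids <- paste0("s", seq_len(nrow(m)))
    dimnames(m) <- list(ids, ids)
  }
  m
}

#' @keywords internal
#' @noRd
upper_pairs <- function(ids) {
  n <- length(ids)
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  data.frame(sample_i = ids[i], sample_j = ids[j], stringsAsFactors = FALSE)
}
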