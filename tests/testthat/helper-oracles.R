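# Independent brute-force oracles. Deliberately naive: plain loops and
# enumeration, sharing no code with the implementations they check.

# patristic distance matrix via node paths (independent of cophenetic use
# in the package: goes through ape::dist.nodes on the full node set)
oracle_patristic <- function(tree) {
  d <- ape::dist.nodes(tree)[seq_along(tree$tip.label), seq_along(tree$tip.label)]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

# MNTD: exhaustive nearest-neighbour scan
oracle_mntd <- function(x, d, abundance_weighted = TRUE) {
  present <- names(x)[x > 0]
  f <- if (abundance_weighted) x[present] / sum(x[present])
       else stats::setNames(rep(1 / length(present), length(present)), present)
  total <- 0
  for (i in present) {
    best <- Inf
    for (j in setdiff(present, i)) best <- min(best, d[i, j])
    total <- total + f[[i]] * best
  }
  total
}

# beta-MNTD: exhaustive double loop
oracle_beta_mntd <- function(x, y, d, abundance_weighted = TRUE) {
  px <- names(x)[x > 0]; py <- names(y)[y > 0]
  fx <- if (abundance_weighted) x[px] / sum(x[px]) else rep(1 / length(px), length(px))
  fy <- if (abundance_weighted) y[py] / sum(y[py]) else rep(1 / length(py), length(py))
  names(fx) <- px; names(fy) <- py
  s1 <- 0
  for (i in px) s1 <- s1 + fx[[i]] * min(vapply(py, function(j) d[i, j], 0))
  s2 <- 0
  for (j in py) s2 <- s2 + fy[[j]] * min(vapply(px, function(i) d[i, j], 0))
  0.5 * (s1 + s2)
}

# unweighted UniFrac by per-branch tally over explicitly enumerated clades
oracle_unifrac_pair <- function(pa, pb, tree) {
  n_tip <- length(tree$tip.label)
  shared_len <- 0; union_len <- 0
  for (k in seq_len(nrow(tree$edge))) {
    child <- tree$edge[k, 2L]
    tips <- if (child <= n_tip) tree$tip.label[child]
            else ape::extract.clade(tree, child)$tip.label
    ina <- any(pa[tips]); inb <- any(pb[tips])
    if (ina || inb) {
      union_len <- union_len + tree$edge.length[k]
      if (xor(ina, inb)) shared_len <- shared_len + tree$edge.length[k]
    }
  }
  shared_len / union_len
}

# Spearman as rank-then-Pearson
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Benjamini-Hochberg step-up, written out longhand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (r in m:1) {
    val <- min(prev, p[o[r]] * m / r)
    q[o[r]] <- val
    prev <- val
  }
  q
}

# --- exact RC_bray by exhaustive enumeration over all null assemblages ----

# probability of drawing the (unordered) id set `subset` without
# replacement with selection probabilities ~ w: sum over all orderings
subset_prob <- function(subset, w) {
  if (length(subset) == 1L) return(unname(w[subset] / sum(w)))
  total <- 0
  for (first in subset) {
    total <- total + unname(w[first] / sum(w)) *
      subset_prob(setdiff(subset, first), w[names(w) != first])
  }
  total
}

# all compositions of `n` into `k` parts
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  out <- NULL
  for (first in 0:n) {
    rest <- compositions(n - first, k - 1L)
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}

# distribution (community matrix + probabilities) of the Raup-Crick null
# for one sample: richness and reads fixed, taxa ~ occupancy without
# replacement, extra reads ~ pool relative abundance among chosen
oracle_rc_null_dist <- function(richness, reads, occ, pool_ab) {
  p <- length(occ)
  names(occ) <- names(pool_ab) <- paste0("t", seq_len(p))
  subsets <- utils::combn(p, richness, simplify = FALSE)
  comms <- list(); probs <- numeric(0)
  for (s in subsets) {
    ps <- subset_prob(names(occ)[s], occ)
    extra <- reads - richness
    if (extra == 0L) {
      x <- integer(p); x[s] <- 1L
      comms[[length(comms) + 1L]] <- x
      probs <- c(probs, ps)
    } else {
      alloc <- compositions(extra, richness)
      ap <- pool_ab[s] / sum(pool_ab[s])
      for (r in seq_len(nrow(alloc))) {
        x <- integer(p); x[s] <- 1L + alloc[r, ]
        comms[[length(comms) + 1L]] <- x
        probs <- c(probs, ps * stats::dmultinom(alloc[r, ], extra, ap))
      }
    }
  }
  list(comms = do.call(rbind, comms), probs = probs)
}

oracle_bc <- function(x, y) sum(abs(x - y)) / sum(x + y)

# exact expected RC_bray for a 2-sample count matrix
oracle_rc_bray_exact <- function(counts) {
  occ <- colSums(counts > 0)
  pool_ab <- colSums(counts) / sum(counts)
  d1 <- oracle_rc_null_dist(sum(counts[1, ] > 0), sum(counts[1, ]), occ, pool_ab)
  d2 <- oracle_rc_null_dist(sum(counts[2, ] > 0), sum(counts[2, ]), occ, pool_ab)
  obs <- oracle_bc(counts[1, ], counts[2, ])
  p_less <- 0; p_tie <- 0
  for (i in seq_len(nrow(d1$comms))) {
    for (j in seq_len(nrow(d2$comms))) {
      bc <- oracle_bc(d1$comms[i, ], d2$comms[j, ])
      pr <- d1$probs[i] * d2$probs[j]
      if (bc < obs - 1e-12) p_less <- p_less + pr
      else if (abs(bc - obs) <= 1e-12) p_tie <- p_tie + pr
    }
  }
  2 * ((p_less + 0.5 * p_tie) - 0.5)
}

# small deterministic count fixture
toy_counts <- function() {
  m <- matrix(c(3L, 0L, 1L, 2L,
                1L, 2L, 0L, 4L,
                0L, 5L, 2L, 1L), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), paste0("t", 1:4)))
  m
}
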