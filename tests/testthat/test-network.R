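test_that("dominant-taxon filtering applies the mean relative-abundance rule", {
  # taxon A at 0.6% mean relative abundance survives, B at 0.4% is dropped
  filler <- 9900L
  m <- matrix(c(60L, 40L, filler,
                60L, 40L, filler), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  kept <- filter_dominant(m, threshold = 0.005)
  expect_true("A" %in% colnames(kept))
  expect_false("B" %in% colnames(kept))
  expect_error(filter_dominant(m, threshold = 0), "\\(0, 1\\)")
  # independent scan on a synthetic table
  ds <- generate_dataset(synthetic_scenario(n_taxa = 200, depth = 2000,
                                            regime = "neutral", seed = 14))
  rel <- sweep(ds$counts, 1, rowSums(ds$counts), "/")
  expect_equal(ncol(filter_dominant(ds$counts)), sum(colMeans(rel) > 0.005))
})

test_that("pairwise metrics agree with direct and rank-based oracles", {
  m <- guild_counts(n_samples = 10, guild_size = 3, n_background = 4)
  met <- pairwise_metrics(m)
  rel <- sweep(m, 1, rowSums(m), "/")
  for (k in c(1, 10, 20)) {
    a <- rel[, met$taxon_a[k]]; b <- rel[, met$taxon_b[k]]
    expect_equal(met$pearson_r[k], stats::cor(a, b), tolerance = 1e-12)
    expect_equal(met$spearman_rho[k], oracle_spearman(a, b), tolerance = 1e-12)
    expect_equal(met$bray_curtis_sim[k],
                 1 - sum(abs(a - b)) / sum(a + b), tolerance = 1e-12)
  }
  # self-association sanity and identical profiles
  expect_equal(stats::cor(rel[, 1], rel[, 1]), 1)
  dup <- cbind(m, dup_of_1 = m[, 1])
  met2 <- pairwise_metrics(dup)
  row <- met2[met2$taxon_a == colnames(m)[1] & met2$taxon_b == "dup_of_1", ]
  expect_equal(row$pearson_r, 1)        # identical raw profile
  expect_gt(row$bray_curtis_sim, 0.99)  # relative abundances differ only by scaling
})

test_that("zero-variance taxa are excluded and flagged", {
  m <- matrix(c(5L, 1L, 7L,
                5L, 2L, 3L,
                5L, 3L, 9L,
                5L, 4L, 2L), 4, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), c("flat", "up", "noisy")))
  # flat = up + noisy makes its relative abundance exactly 0.5 everywhere
  m[, "flat"] <- m[, "up"] + m[, "noisy"]
  met <- pairwise_metrics(m)
  expect_identical(attr(met, "excluded_taxa"), "flat")
  expect_false("flat" %in% c(met$taxon_a, met$taxon_b))
})

test_that("permutation p-values hit the extreme bound and reproduce with seed", {
  set.seed(7)
  x <- as.integer(1:12 * 3)
  m <- cbind(a = x, b = as.integer(x * 2), c = rpois(12, 20) + 1L)
  rownames(m) <- paste0("s", 1:12)
  pv <- permutation_pvalues(m, n_perm = 999, seed = 1)
  row <- pv[pv$taxon_a == "a" & pv$taxon_b == "b", ]
  expect_equal(row$p_spearman, 0.001)
  pv2 <- permutation_pvalues(m, n_perm = 999, seed = 1)
  expect_identical(pv, pv2)
})

test_that("permutation p-values are roughly uniform for independent taxa", {
  set.seed(17)
  m <- matrix(rpois(12 * 30, 20) + 1L, 12, 30,
              dimnames = list(paste0("s", 1:12), paste0("t", 1:30)))
  pv <- permutation_pvalues(m, n_perm = 199, seed = 3)
  ks <- suppressWarnings(stats::ks.test(pv$p_pearson, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("Brown's merge reduces to Fisher at zero correlation", {
  p <- c(0.03, 0.2, 0.7)
  fisher <- stats::pchisq(-2 * sum(log(p)), df = 6, lower.tail = FALSE)
  expect_lt(abs(browns_merge(p, diag(3)) - fisher), 1e-10)
})

test_that("Brown's merge treats fully redundant evidence as one test", {
  r <- matrix(1, 2, 2)
  expect_equal(browns_merge(c(0.05, 0.05), r), 0.05, tolerance = 1e-3)
})

test_that("Brown's merge is monotone in each input p-value", {
  r <- matrix(c(1, 0.5, 0.3, 0.5, 1, 0.4, 0.3, 0.4, 1), 3, 3)
  grid <- seq(0.01, 0.99, by = 0.07)
  for (k in 1:3) {
    base <- c(0.2, 0.3, 0.4)
    vals <- vapply(grid, function(p) {
      x <- base; x[k] <- p; browns_merge(x, r)
    }, numeric(1))
    expect_true(all(diff(vals) > 0))
  }
  expect_error(browns_merge(c(0, 0.5), diag(2)), "\\(0, 1\\]")
})

test_that("BH adjustment matches the longhand step-up computation", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_adjust(p), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  set.seed(23)
  p2 <- runif(17)
  expect_equal(bh_adjust(p2), oracle_bh(p2), tolerance = 1e-12)
})

test_that("edge gates require both the rho magnitude and the q threshold", {
  edges <- data.frame(taxon_a = c("a", "b", "c"), taxon_b = c("x", "y", "z"),
                      spearman_rho = c(0.61, -0.7, 0.9),
                      sign = c("positive", "negative", "positive"),
                      q = c(0.005, 0.005, 0.02))
  g <- build_network(edges, rho_threshold = 0.6, q_threshold = 0.01)
  kept <- graph_edges(g)
  expect_equal(nrow(kept), 2L)
  expect_setequal(kept$sign, c("pos", "neg"))
  expect_false("c" %in% c(kept$taxon_a, kept$taxon_b))
})

test_that("network summaries derive totals, density and degree correctly", {
  s <- network_summary(49, 100, 73)
  expect_equal(s$total_links, 173L)
  expect_equal(round(100 * s$pct_positive, 2), 57.80)
  expect_equal(s$density, 2 * 173 / (49 * 48))
  expect_equal(s$average_degree, 2 * 173 / 49)
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  igraph::E(tri)$sign <- "positive"
  st <- topology(tri)
  expect_equal(st$density, 1.0)
  expect_equal(st$average_degree, 2.0)
  empty <- topology(igraph::make_empty_graph(0, directed = FALSE))
  expect_equal(empty$n_nodes, 0L)
  expect_equal(empty$total_links, 0L)
})

test_that("module detection recovers two disjoint triangles with closed-form Q", {
  g <- igraph::graph_from_literal(a - b, b - c, c - a, x - y, y - z, z - x)
  part <- detect_modules(g, seed = 1)
  expect_equal(length(unique(part$membership)), 2L)
  expect_equal(part$modularity, 0.5, tolerance = 1e-12)
  # keystones: within-module degree is 2 for every node; top-2 returned
  expect_length(keystone_taxa(g, part, top_k = 2), 2L)
})

test_that("planted guilds are recovered as all-positive modules", {
  m <- guild_counts()
  net <- cooccurrence_network(m, dominance_threshold = 0.005,
                              rho_threshold = 0.6, q_threshold = 0.01,
                              n_perm = 499, seed = 1)
  kept <- graph_edges(net$graph)
  guild_of <- function(x) sub("_.*", "", x)
  within <- guild_of(kept$taxon_a) == guild_of(kept$taxon_b) &
    guild_of(kept$taxon_a) %in% c("g1", "g2")
  expect_true(all(kept$sign[within] == "pos"))
  memb <- net$partition$membership
  nodes <- names(memb)[guild_of(names(memb)) %in% c("g1", "g2")]
  ari <- mclust::adjustedRandIndex(memb[nodes], guild_of(nodes))
  expect_gt(ari, 0.8)
})
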