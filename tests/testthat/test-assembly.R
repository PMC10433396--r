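test_that("MNTD matches hand-computable cases and the brute-force scan", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  x <- c(A = 3, B = 0, C = 1)  # A and C at patristic distance 4
  expect_equal(mntd(x, tree), 4)
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1);")
  expect_equal(mntd(c(a = 9, b = 1, c = 4, d = 2, e = 1), star), 2)
  expect_equal(mntd(c(a = 1, b = 1, c = 1, d = 1, e = 1), star,
                    abundance_weighted = FALSE), 2)
  set.seed(21)
  tr5 <- ape::rtree(5); tr5$tip.label <- paste0("t", 1:5)
  y <- c(t1 = 4, t2 = 0, t3 = 1, t4 = 2, t5 = 7)
  d <- oracle_patristic(tr5)
  expect_equal(mntd(y, tr5), oracle_mntd(y, d), tolerance = 1e-12)
  expect_equal(mntd(y, tr5, abundance_weighted = FALSE),
               oracle_mntd(y, d, abundance_weighted = FALSE), tolerance = 1e-12)
  expect_error(mntd(c(A = 1, B = 0, C = 0), tree), "at least 2")
})

test_that("beta-MNTD matches the exhaustive double-loop oracle and picante", {
  set.seed(31)
  tree <- ape::rtree(8); tree$tip.label <- paste0("t", 1:8)
  counts <- matrix(c(0L, 0L, 3L, 1L, 2L, 0L, 4L, 1L,
                     2L, 1L, 0L, 3L, 0L, 1L, 0L, 2L,
                     1L, 4L, 1L, 0L, 2L, 2L, 1L, 0L), 3, 8, byrow = TRUE,
                   dimnames = list(paste0("s", 1:3), tree$tip.label))
  bm <- as.matrix(beta_mntd(counts, tree))
  d <- oracle_patristic(tree)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(bm[i, j], oracle_beta_mntd(counts[i, ], counts[j, ], d),
                 tolerance = 1e-12)
  }
  orc <- picante::comdistnt(counts, stats::cophenetic(tree),
                            abundance.weighted = TRUE)
  expect_equal(as.numeric(beta_mntd(counts, tree)), as.numeric(orc),
               tolerance = 1e-12)
})

test_that("beta-MNTD is 0 for identical communities and the patristic distance for singletons", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  counts <- matrix(c(2L, 1L, 3L,
                     2L, 1L, 3L,
                     5L, 0L, 0L,
                     0L, 0L, 7L), 4, 3, byrow = TRUE,
                   dimnames = list(paste0("s", 1:4), c("A", "B", "C")))
  bm <- as.matrix(beta_mntd(counts, tree))
  expect_equal(bm["s1", "s2"], 0)
  expect_equal(bm["s3", "s4"], 4)  # singleton communities A vs C
})

test_that("ses.MNTD flags degenerate nulls and is seed-reproducible", {
  tree <- simulate_tree(12, seed = 2)
  full <- matrix(rep(1L, 12), 1, 12,
                 dimnames = list("s1", tree$tip.label))
  counts <- rbind(full, s2 = c(rep(1L, 5), rep(0L, 7)))
  rownames(counts) <- c("s1", "s2")
  expect_warning(res <- ses_mntd(counts, tree, n_null = 99, seed = 1),
                 "degenerate")
  expect_true(is.na(res$ses_mntd[res$sample_id == "s1"]))
  expect_false(is.na(res$ses_mntd[res$sample_id == "s2"]))
  expect_equal(res$nti, -res$ses_mntd)
  again <- suppressWarnings(ses_mntd(counts, tree, n_null = 99, seed = 1))
  expect_identical(res$ses_mntd, again$ses_mntd)
})

test_that("ses.MNTD is approximately standard normal under a random null", {
  # random communities on random trees: the standardized effect size should
  # be centred near 0 with roughly unit spread
  ses <- vapply(seq_len(120), function(i) {
    tree <- simulate_tree(15, seed = 5000 + i)
    set.seed(6000 + i)
    x <- matrix(0L, 1, 15, dimnames = list("s", tree$tip.label))
    x[1, sample(15, 6)] <- rpois(6, 3) + 1L
    ses_mntd(x, tree, n_null = 99, seed = 7000 + i)$ses_mntd
  }, numeric(1))
  expect_lt(abs(mean(ses)), 0.15)
  expect_gt(stats::sd(ses), 0.75)
  expect_lt(stats::sd(ses), 1.25)
})

test_that("beta-NTI is invariant to taxon and sample order and flags identical pairs", {
  ds <- generate_dataset(synthetic_scenario(n_taxa = 40, depth = 400,
                                            regime = "neutral", seed = 4))
  bn <- suppressWarnings(beta_nti(ds$counts, ds$tree, n_null = 99, seed = 3))
  perm_t <- sample(ncol(ds$counts)); perm_s <- sample(nrow(ds$counts))
  bn2 <- suppressWarnings(
    beta_nti(ds$counts[perm_s, perm_t], ds$tree, n_null = 99, seed = 3))
  m1 <- as.matrix(bn$beta_nti); m2 <- as.matrix(bn2$beta_nti)
  expect_equal(m2[rownames(m1), colnames(m1)], m1, tolerance = 1e-12)
  dup <- ds$counts[c(1, 1, 2), ]
  rownames(dup) <- c("a", "b", "c")
  expect_warning(bd <- beta_nti(dup, ds$tree, n_null = 99, seed = 3),
                 "degenerate")
  expect_true(is.na(as.matrix(bd$beta_nti)["a", "b"]))
})

test_that("RC_bray converges to the exhaustive enumeration oracle", {
  counts <- matrix(c(2L, 1L, 0L, 1L,
                     0L, 2L, 1L, 1L), 2, 4, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), paste0("t", 1:4)))
  exact <- oracle_rc_bray_exact(counts)
  mc <- as.numeric(rc_bray(counts, n_null = 999, seed = 1))
  expect_lt(abs(mc - exact), 0.05)
  expect_error(rc_bray(matrix(5L, 2, 1, dimnames = list(c("a", "b"), "t")),
                       n_null = 99), "at least 2 taxa")
})

test_that("RC_bray approaches its boundaries for extreme observed dissimilarity", {
  # two disjoint dominant blocks: observed BC is 1, above every null draw
  # except the occasional disjoint null (which ties and takes half weight)
  counts <- matrix(0L, 2, 8, dimnames = list(c("s1", "s2"), paste0("t", 1:8)))
  counts[1, 1:4] <- 50L
  counts[2, 5:8] <- 50L
  expect_gte(as.numeric(rc_bray(counts, n_null = 199, seed = 2)), 0.99)
  # identical heavy overlap: observed BC below the null
  counts2 <- matrix(c(80L, 80L, 80L, 80L, 1L, 0L,
                      80L, 80L, 80L, 80L, 0L, 1L), 2, 6, byrow = TRUE,
                    dimnames = list(c("s1", "s2"), paste0("t", 1:6)))
  expect_equal(as.numeric(rc_bray(counts2, n_null = 199, seed = 2)), -1)
})

test_that("the five-way classifier applies the threshold rules", {
  eps <- 1e-6
  b <- c(-3.1, 1.0, 0.0, -1.0, 2 + eps, -2 - eps, 2 - eps, -2 + eps, 1, 1)
  r <- c(0.5, 0.99, 0.0, -0.99, -0.5, 0.99, 0.95 + eps, 0.95 - eps,
         -0.95 - eps, -0.95 + eps)
  got <- classify_assembly(b, r)
  expect_equal(as.character(got),
               c("homogeneous_selection", "dispersal_limitation", "drift",
                 "homogenizing_dispersal", "variable_selection",
                 "homogeneous_selection", "dispersal_limitation", "drift",
                 "homogenizing_dispersal", "drift"))
  expect_true(is.na(classify_assembly(NA_real_, 0.5)[1]))
})

test_that("process summaries reproduce fraction arithmetic and scope", {
  lab <- factor(c(rep("homogeneous_selection", 58), rep("drift", 8)),
                levels = c("variable_selection", "homogeneous_selection",
                           "dispersal_limitation", "homogenizing_dispersal",
                           "drift"))
  s <- summarize_processes(lab)
  expect_equal(s$deterministic_fraction, 58 / 66, tolerance = 1e-12)
  expect_equal(s$stochastic_fraction, 8 / 66, tolerance = 1e-12)
  expect_equal(round(100 * s$deterministic_fraction, 2), 87.88)
  expect_equal(round(100 * s$stochastic_fraction, 2), 12.12)
  fr <- unlist(s[grepl("^frac_", names(s))])
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  one <- summarize_processes(factor(rep("drift", 5),
                                    levels = levels(lab)))
  expect_equal(one$frac_drift, 1)
  expect_equal(one$deterministic_fraction, 0)
  # within-group scope
  ids <- paste0("s", 1:4)
  groups <- stats::setNames(c("A", "A", "B", "B"), ids)
  pairs <- data.frame(sample_i = c("s1", "s1", "s1", "s2", "s2", "s3"),
                      sample_j = c("s2", "s3", "s4", "s3", "s4", "s4"))
  lab6 <- factor(c("drift", "homogeneous_selection", "drift",
                   "drift", "drift", "homogeneous_selection"),
                 levels = levels(lab))
  w <- summarize_processes(lab6, groups, pairs, scope = "within_group")
  expect_equal(w$scope, c("A", "B"))
  expect_equal(w$frac_drift, c(1, 0))
  expect_equal(w$frac_homogeneous_selection, c(0, 1))
})

test_that("Mantel test recovers perfect correlation with exact p resolution", {
  set.seed(9)
  pts <- matrix(rnorm(14), 7, 2, dimnames = list(paste0("s", 1:7), NULL))
  d1 <- dist(pts)
  res <- mantel_test(d1, 2 * d1, n_perm = 999, seed = 1)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$p, 1 / 1000)
  expect_true(abs(res$p * 1000 - round(res$p * 1000)) < 1e-9)
  bad <- dist(matrix(rnorm(10), 5, 2,
                     dimnames = list(paste0("x", 1:5), NULL)))
  expect_error(mantel_test(d1, bad), "different ids")
})

test_that("Mantel p-values are roughly uniform under independence", {
  ps <- vapply(seq_len(80), function(i) {
    set.seed(100 + i)
    a <- dist(matrix(rnorm(20), 10, 2))
    b <- dist(matrix(rnorm(20), 10, 2))
    mantel_test(a, b, n_perm = 99, seed = 200 + i)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("the full assembly pipeline labels pairs and groups coherently", {
  ds <- generate_dataset(synthetic_scenario(n_taxa = 60, depth = 400,
                                            regime = "neutral", seed = 12))
  asm <- suppressWarnings(
    community_assembly(ds$counts, ds$tree, ds$groups, n_null = 99, seed = 1))
  expect_s3_class(asm, "community_assembly")
  expect_equal(nrow(asm$pairs), choose(12, 2))
  expect_true(all(abs(asm$pairs$rc_bray) <= 1))
  within <- asm$pairs$group_context != "between"
  expect_equal(sum(within), 12L)  # 4 groups x choose(3,2)
  expect_equal(asm$summary_overall$n_pairs + asm$summary_overall$n_excluded,
               nrow(asm$pairs))
  expect_output(print(asm), "deterministic")
})
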