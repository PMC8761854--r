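# exhaustive branch-walk unweighted UniFrac for small trees: classify every
# edge by the tips below it and ratio unique/total branch length
unifrac_oracle <- function(counts_row_a, counts_row_b, tree) {
  tips_below <- phangorn::Descendants(tree, tree$edge[, 2], "tips")
  a_tips <- tree$tip.label[match(names(counts_row_a)[counts_row_a > 0], tree$tip.label)]
  b_tips <- tree$tip.label[match(names(counts_row_b)[counts_row_b > 0], tree$tip.label)]
  in_a <- vapply(tips_below, function(tp) any(tree$tip.label[tp] %in% a_tips), logical(1))
  in_b <- vapply(tips_below, function(tp) any(tree$tip.label[tp] %in% b_tips), logical(1))
  len <- tree$edge.length
  sum(len[xor(in_a, in_b)]) / sum(len[in_a | in_b])
}

test_that("shannon follows the entropy formula and its edge cases", {
  expect_equal(shannon(c(10, 0, 0)), 0)
  expect_equal(shannon(c(5, 5, 5, 5)), log(4))
  expect_equal(shannon(c(5, 3, 2)), 1.0296530140645737)  # hand evaluation
  expect_equal(shannon(c(5, 3, 2), base = 2), 1.0296530140645737 / log(2))
  expect_error(shannon(c(0, 0)), "all-zero")
  # agrees with vegan and is maximal at uniform composition
  x <- c(9, 1, 4, 7, 2)
  expect_equal(shannon(x), unname(vegan::diversity(x)))
  for (i in 1:20) {
    y <- sample(1:50, 6)
    expect_lte(shannon(y), shannon(rep(10, 6)))
  }
})

test_that("chao1 matches its closed form and the vegan estimator", {
  expect_equal(chao1(c(5, 5, 5)), 3)  # no singletons -> observed
  x <- c(rep(5, 6), 1, 1, 1, 2)      # S_obs 10, F1 = 3, F2 = 1
  expect_equal(chao1(x), 11.5)
  expect_equal(chao1(c(x, 0)), 11.5)  # zero column leaves estimate unchanged
  expect_equal(chao1(x), unname(vegan::estimateR(x)["S.chao1"]))
  expect_equal(chao1(c(1, 1, 5), bias_corrected = FALSE), 4)  # F2=0 fallback
  expect_gte(chao1(x), sum(x > 0))
})

test_that("alpha diversity table is per-sample and internally consistent", {
  coh <- small_cohort()
  a <- alpha_diversity(coh$counts)
  expect_identical(a$sample_id, coh$counts$sample_id)
  expect_true(all(a$chao1 >= a$observed))
  expect_true(all(a$shannon >= 0))
})

test_that("unweighted unifrac matches the exhaustive branch oracle", {
  set.seed(42)
  for (rep in 1:10) {
    tree <- ape::rtree(5, tip.label = sprintf("OTU%d", 1:5))
    counts <- matrix(rbinom(10, 8, 0.6), 2, 5,
                     dimnames = list(c("a", "b"), tree$tip.label))
    counts[1, 1] <- pmax(counts[1, 1], 1)  # keep communities non-empty
    counts[2, 2] <- pmax(counts[2, 2], 1)
    d <- unifrac_distance(toy_counts(counts, c("a", "b")), tree)
    expect_equal(as.numeric(d),
                 unifrac_oracle(counts[1, ], counts[2, ], tree))
  }
})

test_that("unifrac hits its boundary values and validates leaves", {
  # star-like rooted tree: zero-length internal edges
  tree <- ape::read.tree(text = "((OTU1:1,OTU2:1):0,(OTU3:1,OTU4:1):0);")
  same <- toy_counts(rbind(c(1, 2, 0, 0), c(5, 9, 0, 0)))
  expect_equal(max(as.numeric(unifrac_distance(same, tree))), 0)
  disjoint <- toy_counts(rbind(c(1, 1, 0, 0), c(0, 0, 2, 3)))
  expect_equal(as.numeric(unifrac_distance(disjoint, tree)), 1)
  expect_error(unifrac_distance(toy_counts(matrix(1, 2, 5)), tree), "OTU5")
})

test_that("unifrac distances are bounded, symmetric metrics on random tables", {
  set.seed(7)
  coh <- small_cohort()
  tree <- coh$tree
  for (rep in 1:10) {
    ids <- sample(coh$counts$sample_id, 6)
    d <- as.matrix(unifrac_distance(
      coh$counts[match(ids, coh$counts$sample_id), ], tree))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    # triangle inequality over all triples
    for (tri in utils::combn(6, 3, simplify = FALSE)) {
      expect_lte(d[tri[1], tri[2]],
                 d[tri[1], tri[3]] + d[tri[3], tri[2]] + 1e-12)
    }
  }
})

test_that("pcoa reproduces planar configurations and keeps negative eigenvalues", {
  set.seed(1)
  xy <- matrix(rnorm(20), 10, 2)
  d <- dist(xy)
  ord <- pcoa_ordination(d, k = 2)
  rec <- as.matrix(ord$scores[, c("Axis1", "Axis2")])
  expect_equal(as.numeric(dist(rec)), as.numeric(d), tolerance = 1e-8)
  # non-Euclidean input: negative eigenvalues are reported
  dm <- matrix(0.9, 4, 4); diag(dm) <- 0; dm[1, 2] <- dm[2, 1] <- 0.05
  ordn <- pcoa_ordination(as.dist(dm), k = 2)
  expect_true(any(ordn$eigenvalues < 0))
  expect_warning(pcoa_ordination(d, k = 10), "axes")
  one <- pcoa_ordination(matrix(0, 1, 1, dimnames = list("s1", "s1")))
  expect_equal(one$scores$Axis1, 0)
})

test_that("pcoa axis 1 separates two planted clusters", {
  dm <- matrix(1, 8, 8)
  dm[1:4, 1:4] <- 0.1; dm[5:8, 5:8] <- 0.1
  diag(dm) <- 0
  rownames(dm) <- colnames(dm) <- sprintf("s%d", 1:8)
  ord <- pcoa_ordination(as.dist(dm), k = 2)
  ax1 <- ord$scores$Axis1
  expect_true(max(ax1[1:4]) < min(ax1[5:8]) || min(ax1[1:4]) > max(ax1[5:8]))
})

test_that("anosim statistic matches vegan and hits boundary cases", {
  # all pairwise distances equal -> R = 0
  dm <- matrix(1, 6, 6); diag(dm) <- 0
  g <- rep(c("a", "b"), each = 3)
  expect_equal(anosim_test(dm, g, n_perm = 49)$statistic, 0)
  # two perfectly separated clusters -> R = 1; with 8 + 8 samples the
  # partition-preserving label permutations are vanishingly rare, so the
  # permutation p hits its floor
  dm2 <- matrix(1, 16, 16); dm2[1:8, 1:8] <- 0.1; dm2[9:16, 9:16] <- 0.1; diag(dm2) <- 0
  g2 <- rep(c("a", "b"), each = 8)
  res <- anosim_test(dm2, g2, n_perm = 99, seed = 3)
  expect_equal(res$statistic, 1)
  expect_equal(res$p_value, 1 / 100)
  # statistic agrees with vegan on random data
  set.seed(5)
  for (rep in 1:5) {
    x <- matrix(rnorm(40), 8)
    d <- dist(x)
    lab <- rep(c("a", "b"), each = 4)
    expect_equal(anosim_test(d, lab, n_perm = 9)$statistic,
                 unname(vegan::anosim(d, lab, permutations = 1)$statistic))
  }
  expect_error(anosim_test(dm, rep("a", 6)), "2 groups")
})

test_that("permanova pseudo-F matches vegan's adonis2 and is monotone", {
  set.seed(9)
  for (rep in 1:5) {
    x <- matrix(rnorm(48), 12)
    d <- dist(x)
    lab <- rep(c("a", "b"), each = 6)
    f_mine <- permanova_test(d, lab, n_perm = 9)$statistic
    f_vegan <- vegan::adonis2(d ~ lab, permutations = 2)$F[1]
    expect_equal(f_mine, f_vegan)
  }
  # scaling up separation strictly increases pseudo-F
  set.seed(31)
  base <- matrix(rnorm(40), 10)
  lab <- rep(c("a", "b"), each = 5)
  fs <- vapply(c(0, 2, 5), function(sh) {
    y <- base; y[lab == "b", ] <- y[lab == "b", ] + sh
    permanova_test(dist(y), lab, n_perm = 9)$statistic
  }, numeric(1))
  expect_true(all(diff(fs) > 0))
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(13)
  ps <- vapply(1:120, function(i) {
    x <- matrix(rnorm(40), 10)
    lab <- sample(rep(c("a", "b"), each = 5))
    permanova_test(dist(x), lab, n_perm = 59, seed = i)$p_value
  }, numeric(1))
  # rejection rate at 0.05 within 3 binomial SDs of nominal
  expect_lt(abs(mean(ps <= 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 120) + 1e-9)
  ps2 <- vapply(1:120, function(i) {
    x <- matrix(rnorm(40), 10)
    lab <- sample(rep(c("a", "b"), each = 5))
    anosim_test(dist(x), lab, n_perm = 59, seed = i)$p_value
  }, numeric(1))
  expect_lt(abs(mean(ps2 <= 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 120) + 1e-9)
})

test_that("community tests are invariant to a consistent sample relabelling", {
  set.seed(21)
  x <- matrix(rnorm(48), 12)
  d <- as.matrix(dist(x))
  rownames(d) <- colnames(d) <- sprintf("s%d", 1:12)
  lab <- rep(c("a", "b"), each = 6)
  perm <- sample(12)
  r1 <- anosim_test(d, lab, n_perm = 99, seed = 1)
  r2 <- anosim_test(d[perm, perm], lab[perm], n_perm = 99, seed = 1)
  expect_equal(r1$statistic, r2$statistic)
  f1 <- permanova_test(d, lab, n_perm = 99, seed = 1)
  f2 <- permanova_test(d[perm, perm], lab[perm], n_perm = 99, seed = 1)
  expect_equal(f1$statistic, f2$statistic)
})
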