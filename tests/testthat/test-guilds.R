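# exact two-sided rank-sum p by enumerating every assignment of the pooled
# observations to the two groups
wilcox_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  w_obs <- sum(rank(pooled)[seq_along(x)])
  ws <- apply(utils::combn(n, length(x)), 2,
              function(ix) sum(rank(pooled)[ix]))
  mu <- mean(ws)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

test_that("the abundance/prevalence filter applies both rules", {
  # 5 samples; OTU_a: total 999 & prevalent -> out; OTU_b: total 5000 but
  # prevalence 1/5 -> out at 20% threshold only if below it
  counts <- toy_counts(cbind(
    OTU_a = c(500, 499, 0, 0, 0),
    OTU_b = c(5000, 0, 0, 0, 0),
    OTU_c = c(600, 600, 0, 0, 0)
  ))
  kept <- suppressMessages(filter_otus(counts, min_total = 1000, min_prevalence = 0.3))
  expect_identical(setdiff(names(kept), "sample_id"), "OTU_c")
  # prevalence exactly at threshold is retained; just under is dropped
  counts2 <- toy_counts(cbind(OTU_a = c(2000, 0, 0, 0, 0),
                              OTU_b = c(1000, 1000, 0, 0, 0)))
  kept2 <- suppressMessages(filter_otus(counts2, 1000, 0.4))
  expect_identical(setdiff(names(kept2), "sample_id"), "OTU_b")
  # all passing -> identity
  expect_identical(suppressMessages(filter_otus(counts, 1, 0)), counts)
  expect_error(filter_otus(counts, min_total = 1e9), "no OTUs")
})

test_that("sparcc concentrates near zero for independent basis components", {
  set.seed(4)
  n <- 500; p <- 50
  basis <- matrix(exp(rnorm(n * p, 0, 1)), n, p)
  counts <- toy_counts(t(apply(basis, 1, function(r) {
    as.numeric(rmultinom(1, 20000, r / sum(r)))
  })))
  fit <- sparcc(counts, n_iter = 5, n_bootstraps = 0, seed = 1)
  off <- fit$rho[lower.tri(fit$rho)]
  expect_lte(mean(abs(off)), 0.05)
  expect_gte(mean(abs(off) < 0.15), 0.95)
  expect_true(all(fit$omega > 0))
  expect_equal(fit$rho, t(fit$rho))
  expect_true(all(abs(fit$rho) <= 1))
})

test_that("sparcc recovers a planted basis correlation", {
  set.seed(8)
  n <- 300; p <- 20; rho_true <- 0.8
  z1 <- rnorm(n); z2 <- rho_true * z1 + sqrt(1 - rho_true^2) * rnorm(n)
  logb <- cbind(z1, z2, matrix(rnorm(n * (p - 2)), n))
  counts <- toy_counts(t(apply(exp(logb), 1, function(r) {
    as.numeric(rmultinom(1, 30000, r / sum(r)))
  })))
  fit <- sparcc(counts, n_iter = 10, n_bootstraps = 40, seed = 2)
  expect_lt(abs(fit$rho[1, 2] - rho_true), 0.1)
  expect_lt(fit$p_value[1, 2], 0.05)
})

test_that("sparcc point-estimate mode is invariant to sample order", {
  coh <- small_cohort()
  counts <- coh$counts[, 1:25]
  fit1 <- suppressMessages(sparcc(counts, n_iter = 1, n_bootstraps = 0, seed = 1))
  perm <- sample(nrow(counts))
  fit2 <- suppressMessages(sparcc(counts[perm, ], n_iter = 1, n_bootstraps = 0, seed = 1))
  expect_equal(fit1$rho, fit2$rho)
  expect_error(sparcc(counts), "seed")
  expect_error(sparcc(counts[, 1:4], seed = 1), "4 OTUs")
})

test_that("cag clustering separates perfect blocks and degenerate cuts", {
  p <- 12
  rho <- matrix(0, p, p)
  rho[1:6, 1:6] <- 0.9; rho[7:12, 7:12] <- 0.9; diag(rho) <- 1
  dimnames(rho) <- list(sprintf("OTU%02d", 1:p), sprintf("OTU%02d", 1:p))
  part <- cluster_cags(list(rho = rho), n_cags = 2)
  truth <- rep(c(1, 2), each = 6)
  expect_equal(ari(part$map$cag, truth), 1)
  # singleton partition
  single <- cluster_cags(list(rho = rho), n_cags = p)
  expect_equal(length(single$members), p)
  expect_error(cluster_cags(list(rho = rho), n_cags = p + 1), "exceeds")
})

test_that("cag clustering recovers planted guilds and ignores input order", {
  coh <- small_cohort()
  counts <- suppressMessages(filter_otus(coh$counts, 100, 0.2))
  fit <- suppressMessages(sparcc(counts, n_iter = 10, n_bootstraps = 0, seed = 1))
  part <- cluster_cags(fit, n_cags = 6)
  # well above chance on this deliberately small fixture; study-scale
  # recovery is asserted on the full default cohort elsewhere
  expect_gte(ari(part$map$cag, coh$truth$otu_guild_labels[part$map$otu_id]), 0.55)
  # shuffling OTU columns leaves the partition unchanged
  shuf <- sample(ncol(fit$rho))
  part2 <- cluster_cags(list(rho = fit$rho[shuf, shuf]), n_cags = 6)
  expect_identical(part$map, part2$map)
})

test_that("cag abundances close to one and z-scores standardise", {
  coh <- small_cohort()
  counts <- coh$counts
  fit <- suppressMessages(sparcc(counts, n_iter = 5, n_bootstraps = 0, seed = 1))
  part <- cluster_cags(fit, n_cags = 6)
  ab <- cag_abundance(counts, part)
  sums <- rowSums(as.matrix(ab$abundance[, -1]))
  expect_equal(sums, rep(1, length(sums)), ignore_attr = TRUE)
  z <- as.matrix(ab$zscore[, -1])
  expect_equal(unname(colMeans(z)), rep(0, ncol(z)), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, ncol(z)), tolerance = 1e-12)
  # permuting OTU order leaves the result unchanged
  perm <- c(1, sample(2:ncol(counts)))
  ab2 <- cag_abundance(counts[, perm], part)
  expect_equal(ab$abundance, ab2$abundance)
})

test_that("degenerate cag abundance cases are flagged", {
  counts <- toy_counts(cbind(OTU1 = c(5, 10), OTU2 = c(5, 10)))
  part <- list(map = tibble::tibble(otu_id = c("OTU1", "OTU2"),
                                    cag = c("CAG1", "CAG1")))
  expect_warning(ab <- cag_abundance(counts, part), "constant")
  expect_equal(as.numeric(ab$abundance$CAG1), c(1, 1))
  expect_equal(as.numeric(ab$zscore$CAG1), c(0, 0))
  # two-sample hand case with the n-1 sd convention: z = +/- 1/sqrt(2)
  counts2 <- toy_counts(cbind(OTU1 = c(8, 2), OTU2 = c(2, 8)))
  part2 <- list(map = tibble::tibble(otu_id = c("OTU1", "OTU2"),
                                     cag = c("CAG1", "CAG2")))
  ab2 <- cag_abundance(counts2, part2)
  expect_equal(as.numeric(ab2$zscore$CAG1), c(1, -1) / sqrt(2))
})

test_that("cag group tests match exhaustive rank-sum enumeration", {
  set.seed(6)
  for (rep in 1:5) {
    x <- round(runif(3, 0, 10), 1); y <- round(runif(3, 0, 10), 1)
    tab <- toy_counts(cbind(CAG1 = c(x, y), OTU = 1), sprintf("s%d", 1:6))
    res <- test_cag_differences(tab[, 1:2], rep(c("g1", "g2"), each = 3))
    expect_equal(res$p_value[1], wilcox_oracle(y, x))
  }
})

test_that("cag tests flag planted guild shifts with the right direction", {
  coh <- small_cohort()
  counts <- suppressMessages(filter_otus(coh$counts, 100, 0.2))
  fit <- suppressMessages(sparcc(counts, n_iter = 10, n_bootstraps = 0, seed = 1))
  part <- cluster_cags(fit, n_cags = 6)
  ab <- cag_abundance(counts, part)
  grp <- coh$truth$group[ab$abundance$sample_id]
  keep <- grp %in% c("control", "severe")
  res <- test_cag_differences(ab$abundance[keep, ],
                              factor(grp[keep], levels = c("control", "severe")))
  # map planted guilds to the CAG holding most of their members
  lab <- coh$truth$otu_guild_labels[part$map$otu_id]
  hits <- 0
  for (i in seq_len(nrow(coh$truth$affected_guilds))) {
    k <- coh$truth$affected_guilds$guild[i]
    dir <- ifelse(coh$truth$affected_guilds$direction[i] > 0,
                  "increased", "decreased")
    cg <- names(which.max(table(part$map$cag[lab == k])))
    row <- res[res$feature == cg, ]
    hits <- hits + (row$p_value < 0.05 && row$direction == dir)
  }
  expect_gte(hits / nrow(coh$truth$affected_guilds), 0.8)
})

test_that("cag tests are calibrated under exchangeable groups", {
  set.seed(12)
  m <- matrix(rnorm(40 * 100), 40, 100,
              dimnames = list(sprintf("s%d", 1:40), sprintf("CAG%d", 1:100)))
  res <- test_cag_differences(toy_counts(m + 10), rep(c("a", "b"), each = 20))
  expect_lt(abs(mean(res$p_value < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 100) + 1e-9)
  # all-tied feature -> p = 1 with flag
  tied <- toy_counts(cbind(CAG1 = rep(1, 6), CAG2 = rnorm(6) + 5))
  rtied <- test_cag_differences(tied, rep(c("a", "b"), each = 3))
  expect_equal(rtied$p_value[rtied$feature == "CAG1"], 1)
  expect_equal(rtied$flag[rtied$feature == "CAG1"], "all tied")
})
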