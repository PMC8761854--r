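# exact upper-tail hypergeometric p by enumerating overlap probabilities
hyper_oracle <- function(k, pathway_size, universe_size, selected_size) {
  js <- 0:min(pathway_size, selected_size)
  probs <- choose(pathway_size, js) *
    choose(universe_size - pathway_size, selected_size - js) /
    choose(universe_size, selected_size)
  sum(probs[js >= k])
}

test_that("preprocessing imputes, transforms and guards against reapplication", {
  tab <- toy_counts(cbind(m1 = c(100, 1000, 10000),
                          m2 = c(10, 0, 1000),
                          flat = c(5, 5, 5)))
  expect_message(out <- preprocess_metabolites(tab), "constant")
  expect_false("flat" %in% names(out))
  # hand-computed: m1 log10 = 2,3,4 -> centered (-1,0,1), sd = 1 -> unchanged
  expect_equal(out$m1, c(-1, 0, 1))
  # m2: 0 imputed to half-minimum of observed (10/2 = 5) -> log10 = 1, ~0.699, 3
  lm2 <- log10(c(10, 5, 1000))
  expect_equal(out$m2, as.numeric(scale(lm2)))
  expect_error(preprocess_metabolites(out), "already")
  # mostly-missing metabolite is dropped with a note
  tab2 <- toy_counts(cbind(m1 = c(1, 2, 3, 4), m2 = c(0, 0, 0, 5)))
  expect_message(out2 <- preprocess_metabolites(tab2), "50%")
  expect_false("m2" %in% names(out2))
  # pareto scaling divides by sqrt(sd)
  out3 <- preprocess_metabolites(tab[, 1:2], scaling = "pareto")
  expect_equal(out3$m1, c(-1, 0, 1) / sqrt(1))
})

test_that("plsda honours the VIP normalisation identity on arbitrary fits", {
  set.seed(2)
  for (rep in 1:5) {
    x <- toy_counts(matrix(rnorm(30 * 12), 30, 12))
    y <- rep(c("a", "b"), each = 15)
    fit <- plsda_fit(x, y, n_components = 2, n_perm = 0, cv_folds = 5, seed = rep)
    expect_equal(mean(fit$vip$vip^2), 1, tolerance = 1e-6)
    # scores of successive components are orthogonal
    sc <- as.matrix(fit$scores[, c("Comp1", "Comp2")])
    expect_lt(abs(cor(sc[, 1], sc[, 2])), 1e-6)
  }
})

test_that("plsda separates a planted marker and deflates under the null", {
  set.seed(5)
  n <- 40
  x <- matrix(rnorm(n * 20), n, 20)
  y <- rep(c("a", "b"), each = n / 2)
  x[, 7] <- ifelse(y == "a", -2, 2) + rnorm(n, 0, 0.3)  # separating metabolite
  fit <- plsda_fit(toy_counts(x), y, n_perm = 30, seed = 1)
  expect_equal(which.max(fit$vip$vip), 7)
  expect_gt(max(fit$vip$vip), 1)
  expect_gt(fit$q2, 0.5)
  # permutation null sits well below the observed Q2
  expect_gt(fit$q2, max(fit$permutation$q2))
  # independent labels: Q2 near or below zero, null straddles it
  ynull <- sample(y)
  fit0 <- plsda_fit(toy_counts(x[, -7]), ynull, n_perm = 30, seed = 2)
  expect_lte(fit0$q2, 0.05)
  expect_gte(median(fit0$permutation$q2), fit0$q2 - 0.2)
  expect_error(plsda_fit(toy_counts(x), rep("a", n)), "2 classes")
  expect_error(plsda_fit(toy_counts(x), y, cv_folds = 25), "fold")
})

test_that("plsda R2 and VIP agree with the mixOmics reference", {
  skip_if_not_installed("mixOmics")
  set.seed(9)
  n <- 30; p <- 15
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("m%d", 1:p)))
  y <- rep(c("a", "b"), each = n / 2)
  x[, 3] <- x[, 3] + ifelse(y == "a", -1.2, 1.2)
  mine <- plsda_fit(toy_counts(scale(x)), y, n_components = 2, n_perm = 0, seed = 1)
  ref <- mixOmics::plsda(scale(x), factor(y), ncomp = 2)
  vip_ref <- mixOmics::vip(ref)[, 2]
  expect_gt(cor(mine$vip$vip, vip_ref), 0.95)
  expect_equal(which.max(mine$vip$vip), unname(which.max(vip_ref)))
})

test_that("differential metabolite selection applies both rules strictly", {
  set.seed(14)
  n <- 40
  raw <- matrix(rlnorm(n * 10, 5, 0.3), n, 10)
  y <- rep(c("ctrl", "case"), each = n / 2)
  raw[y == "case", 2] <- raw[y == "case", 2] * 2    # elevated
  raw[y == "case", 5] <- raw[y == "case", 5] * 0.4  # suppressed
  tab <- toy_counts(raw)
  proc <- preprocess_metabolites(tab)
  fit <- plsda_fit(proc, factor(y, levels = c("ctrl", "case")), n_perm = 0, seed = 1)
  sel <- select_differential_metabolites(fit, tab, factor(y, levels = c("ctrl", "case")))
  expect_true(sel$selected[2])
  expect_equal(sel$direction[2], "elevated")
  expect_equal(sel$direction[5], "suppressed")
  expect_true(sel$selected[5])
  # VIP exactly at the threshold is not selected
  fake <- fit
  fake$vip$vip <- rep(1, 10)
  sel2 <- select_differential_metabolites(fake, tab, y)
  expect_false(any(sel2$selected))
  # fold change is the raw-scale mean ratio
  fc <- mean(raw[y == "case", 2]) / mean(raw[y == "ctrl", 2])
  expect_equal(sel$fold_change[2], fc)
})

test_that("module detection recovers planted blocks exactly", {
  set.seed(6)
  n <- 60
  lat <- matrix(rnorm(2 * n), 2, n)
  blocks <- do.call(rbind, lapply(1:20, function(i) {
    lat[ifelse(i <= 10, 1, 2), ] + rnorm(n, 0, 0.4)
  }))
  x <- exp(t(blocks))
  colnames(x) <- sprintf("met%02d", 1:20)  # padded: sort order = position
  tab <- toy_counts(x)
  proc <- preprocess_metabolites(tab)
  mods <- suppressMessages(detect_modules(proc, min_module_size = 5))
  truth <- rep(c(1, 2), each = 10)
  expect_equal(ari(mods$map$module, truth), 1)
  # eigen-metabolites align with their latents
  for (md in c("M1", "M2")) {
    members <- which(mods$map$module == md)
    lat_ix <- truth[members[1]]
    expect_gte(abs(cor(mods$eigen[[md]], lat[lat_ix, ])), 0.9)
  }
  # order invariance
  perm <- c(1, sample(2:21))
  mods2 <- suppressMessages(detect_modules(proc[, perm], min_module_size = 5))
  expect_identical(mods$map, mods2$map)
  expect_error(detect_modules(proc[, 1:6], min_module_size = 5), "too few")
})

test_that("eigen-metabolites maximise explained variance and track sign flips", {
  set.seed(8)
  n <- 50
  lat <- rnorm(n)
  x <- vapply(1:12, function(i) lat + rnorm(n, 0, 0.5), numeric(n))
  colnames(x) <- sprintf("met%02d", 1:12)
  proc <- preprocess_metabolites(toy_counts(exp(x)))
  mods <- suppressMessages(detect_modules(proc, min_module_size = 5))
  eig <- mods$eigen$M1
  sub <- scale(as.matrix(proc[, -1])[, mods$map$module == "M1"])
  var_eig <- var(as.numeric(sub %*% (cor(eig, sub)[1, ] /
                                       sqrt(sum(cor(eig, sub)[1, ]^2)))))
  for (i in 1:200) {
    w <- rnorm(ncol(sub)); w <- w / sqrt(sum(w^2))
    expect_lte(var(as.numeric(sub %*% w)), var_eig + 1e-8)
  }
  # sign alignment: positive mean correlation with members
  expect_gt(mean(cor(eig, sub)), 0)
  # flipping the input flips the eigen-metabolite
  flipped <- proc
  flipped[, -1] <- -flipped[, -1]
  class(flipped) <- class(proc)
  mods_f <- suppressMessages(detect_modules(flipped, min_module_size = 5))
  expect_equal(abs(cor(mods_f$eigen$M1, eig)), 1, tolerance = 1e-10)
})

test_that("pathway enrichment equals exact hypergeometric arithmetic", {
  ann <- tibble::tibble(
    metabolite_id = sprintf("m%d", 1:10),
    pathway = rep(c("P1", "P2"), c(4, 6))
  )
  res <- pathway_enrichment(sprintf("m%d", c(1:4, 5)), ann)
  p1 <- res[res$pathway == "P1", ]
  expect_equal(p1$p_value, 6 / 252)  # C(4,4)*C(6,1)/C(10,5)
  expect_equal(p1$rich_factor, 1)
  expect_equal(p1$hits, 4L)
  # disjoint pathway -> upper tail at k = 0 is 1
  res2 <- pathway_enrichment(sprintf("m%d", 5:6), ann)
  expect_equal(res2$p_value[res2$pathway == "P1"], 1)
  # saturation: selected = universe
  res3 <- pathway_enrichment(sprintf("m%d", 1:10), ann)
  expect_true(all(res3$p_value == 1))
  expect_true(all(res3$rich_factor == 1))
})

test_that("pathway enrichment matches the enumeration oracle on random cases", {
  set.seed(10)
  for (rep in 1:20) {
    n_u <- sample(8:15, 1)
    ids <- sprintf("m%d", seq_len(n_u))
    ann <- tibble::tibble(metabolite_id = ids,
                          pathway = sample(c("P1", "P2", "P3"), n_u, TRUE))
    sel <- sample(ids, sample(2:(n_u - 1), 1))
    res <- pathway_enrichment(sel, ann)
    for (i in seq_len(nrow(res))) {
      expect_equal(res$p_value[i],
                   hyper_oracle(res$hits[i], res$pathway_size[i], n_u,
                                length(sel)),
                   tolerance = 1e-12)
    }
  }
  # guards
  expect_error(pathway_enrichment("zzz", tibble::tibble(
    metabolite_id = "m1", pathway = "P1")), "subset")
  empty <- suppressMessages(pathway_enrichment(
    character(), tibble::tibble(metabolite_id = "m1", pathway = "P1")))
  expect_equal(nrow(empty), 0)
})

test_that("module recovery holds on the synthetic metabolome with couplings", {
  coh <- small_cohort()
  for (cmp in c("fecal", "serum")) {
    proc <- suppressMessages(preprocess_metabolites(coh[[cmp]]))
    mods <- suppressMessages(detect_modules(proc))
    truth <- coh$truth$module_labels[[cmp]][mods$map$metabolite_id]
    expect_gte(ari(mods$map$module, truth), 0.8)
    # each detected module's eigen-metabolite tracks one planted latent
    lat <- coh$truth$module_latents[[cmp]]
    for (md in setdiff(unique(mods$map$module), "unassigned")) {
      cors <- abs(cor(mods$eigen[[md]], t(lat[, mods$eigen$sample_id])))
      expect_gte(max(cors), 0.9)
    }
  }
})
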