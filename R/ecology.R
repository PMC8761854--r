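#' Shannon diversity of a single count vector
#'
#' `H = -sum(p_i * log(p_i))` over positive proportions, in natural-log units
#' by default (the scale on which gut 16S studies typically report values in
#' the 2-4 range for a few hundred OTUs).
#'
#' @param x non-negative count (or abundance) vector.
#' @param base logarithm base; `exp(1)` gives nats.
#' @return Shannon entropy H.
#' @examples
#' shannon(c(5, 5, 5, 5)) # log(4)
#' @export
shannon <- function(x, base = exp(1)) {
  if (any(x < 0)) abort("counts must be non-negative")
  if (sum(x) <= 0) abort("Shannon diversity undefined for an all-zero sample")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p)) / log(base)
}

#' Chao1 richness estimate of a single count vector
#'
#' Bias-corrected form `S_obs + F1*(F1-1) / (2*(F2+1))` by default (F1
#' singletons, F2 doubletons), which stays finite when no doubletons are
#' observed; the classical form `S_obs + F1^2/(2*F2)` is available.
#'
#' @param x non-negative integer count vector.
#' @param bias_corrected use the bias-corrected estimator (default) or the
#'   classical one.
#' @return estimated species richness.
#' @examples
#' chao1(c(rep(5, 8), 1, 1, 1, 2)) # S_obs 12, F1 = 3, F2 = 1
#' @export
chao1 <- function(x, bias_corrected = TRUE) {
  if (any(x < 0)) abort("counts must be non-negative")
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    if (f2 == 0) return(s_obs + f1 * (f1 - 1) / 2)
    s_obs + f1^2 / (2 * f2)
  }
}

#' Per-sample alpha diversity table
#'
#' @param counts sample table of OTU counts (`sample_id` + one numeric column
#'   per OTU).
#' @return tibble with per-sample observed richness, Chao1, Shannon (nats)
#'   and sequencing depth.
#' @export
alpha_diversity <- function(counts) {
  m <- as_sample_matrix(counts)
  tibble(
    sample_id = rownames(m),
    observed = apply(m, 1, function(r) sum(r > 0)),
    chao1 = apply(m, 1, chao1),
    shannon = apply(m, 1, shannon),
    depth = rowSums(m)
  )
}

#' Unweighted UniFrac distances
#'
#' Presence/absence phylogenetic beta diversity: for each sample pair, the
#' fraction of tree branch length leading only to taxa present in exactly one
#' of the two samples, out of the branch length leading to taxa present in
#' either. Computed via [picante::unifrac()] after validating that every OTU
#' is a tree leaf.
#'
#' @param counts sample table of OTU counts.
#' @param tree rooted `ape::phylo` tree whose tips cover the OTUs.
#' @return a `dist` object with entries in \[0, 1\].
#' @export
unifrac_distance <- function(counts, tree) {
  m <- as_sample_matrix(counts)
  missing <- setdiff(colnames(m), tree$tip.label)
  if (length(missing)) {
    abort(paste0("OTUs absent from the tree: ",
                 paste(head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5)))
  }
  tr <- ape::keep.tip(tree, colnames(m))
  picante::unifrac(m, tr)
}

#' Principal coordinates analysis
#'
#' Classical scaling of the Gower-centred squared-distance matrix. Negative
#' eigenvalues are retained and reported rather than silently dropped.
#'
#' @param d a `dist` object (or symmetric matrix) of sample distances.
#' @param k number of axes requested.
#' @return object of class `pcoa_ord` with `scores` (tibble: `sample_id`,
#'   `Axis1`, ...), `eigenvalues` (all of them, including negatives), and
#'   `var_explained` (relative to the sum of positive eigenvalues).
#' @export
pcoa_ordination <- function(d, k = 2) {
  dm <- as.matrix(d)
  ids <- rownames(dm) %||% paste0("s", seq_len(nrow(dm)))
  n <- nrow(dm)
  if (n == 1) {
    return(new_result(list(
      scores = tibble(sample_id = ids, Axis1 = 0),
      eigenvalues = 0, var_explained = NA_real_
    ), "pcoa_ord"))
  }
  a <- -0.5 * dm^2
  centering <- diag(n) - matrix(1 / n, n, n)
  g <- centering %*% a %*% centering
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  pos <- which(e$values > sqrt(.Machine$double.eps) * max(abs(e$values)))
  if (k > length(pos)) {
    warn(sprintf("only %d positive axes available (requested %d)", length(pos), k))
    k <- length(pos)
  }
  scores <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(e$values[pos[seq_len(k)]]), k, k)
  colnames(scores) <- paste0("Axis", seq_len(k))
  new_result(list(
    scores = dplyr::bind_cols(tibble(sample_id = ids),
                              as_tibble(as.data.frame(scores))),
    eigenvalues = e$values,
    var_explained = e$values[pos[seq_len(k)]] / sum(e$values[pos])
  ), "pcoa_ord")
}

#' @export
print.pcoa_ord <- function(x, ...) {
  cat(sprintf("<pcoa_ord> %d samples, %d axes (%.1f%%, %.1f%% ...)\n",
              nrow(x$scores), ncol(x$scores) - 1,
              100 * x$var_explained[1],
              if (length(x$var_explained) > 1) 100 * x$var_explained[2] else NA))
  if (any(x$eigenvalues < 0)) {
    cat(sprintf("  %d negative eigenvalues (min %.3g)\n",
                sum(x$eigenvalues < 0), min(x$eigenvalues)))
  }
  invisible(x)
}

check_grouping <- function(d, labels) {
  n <- attr(as.dist(d), "Size")
  if (length(labels) != n) abort("labels must match the distance matrix size")
  g <- droplevels(as.factor(labels))
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    abort("need at least 2 groups with at least 2 samples each")
  }
  g
}

#' Analysis of similarities (ANOSIM)
#'
#' `R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`
#' over the ranked pairwise distances (Clarke's divisor, which scales R to
#' \[-1, 1\]); the permutation p-value is
#' `(1 + #[R_perm >= R_obs]) / (n_perm + 1)`.
#'
#' @param d sample distance matrix (`dist` or symmetric matrix).
#' @param labels group labels aligned with the samples of `d`.
#' @param n_perm number of label permutations (999 by default).
#' @param seed integer seed for the permutations.
#' @return one-row tibble with `statistic` (R), `p_value`, `n_perm`.
#' @export
anosim_test <- function(d, labels, n_perm = 999, seed = 1) {
  g <- check_grouping(d, labels)
  dv <- as.numeric(as.dist(d))
  rk <- rank(dv)
  n <- length(g)
  same <- as.numeric(dist(as.integer(g))) == 0  # within-group pair indicator
  denom <- n * (n - 1) / 4                      # Clarke's divisor

  r_stat <- function(within) {
    (mean(rk[!within]) - mean(rk[within])) / denom
  }
  obs <- r_stat(same)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    gp <- g[sample(n)]
    r_stat(as.numeric(dist(as.integer(gp))) == 0)
  }, numeric(1))
  tibble(method = "ANOSIM", statistic = obs,
         p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
         n_perm = n_perm)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-factor pseudo-F from within- and between-group sums of squared
#' distances (Anderson's formulation), with a seeded permutation p-value.
#'
#' @inheritParams anosim_test
#' @return one-row tibble with `statistic` (pseudo-F), `p_value`, `n_perm`.
#' @export
permanova_test <- function(d, labels, n_perm = 999, seed = 1) {
  g <- check_grouping(d, labels)
  dm <- as.matrix(as.dist(d))
  n <- nrow(dm)
  a <- nlevels(g)
  ss_total <- sum(dm[lower.tri(dm)]^2) / n

  pseudo_f <- function(g) {
    ss_within <- 0
    for (lev in levels(g)) {
      ix <- which(g == lev)
      sub <- dm[ix, ix, drop = FALSE]
      ss_within <- ss_within + sum(sub[lower.tri(sub)]^2) / length(ix)
    }
    ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
  }
  obs <- pseudo_f(g)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) pseudo_f(g[sample(n)]), numeric(1))
  tibble(method = "PERMANOVA", statistic = obs,
         p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
         n_perm = n_perm)
}
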