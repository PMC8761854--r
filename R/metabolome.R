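#' Preprocess a metabolite intensity table
#'
#' Half-minimum imputation per metabolite (missing = `NA` or 0), `log10`
#' transform, then column scaling to zero mean and unit variance (or Pareto
#' scaling). Metabolites that are entirely missing, missing in at least half
#' the samples, or constant are dropped with a note. The transform is
#' recorded and a second application errors.
#'
#' @param table sample table of positive intensities.
#' @param scaling `"unit"` (autoscaling, default) or `"pareto"`.
#' @return the processed sample table, with attribute `metab_transform`
#'   describing the steps and class `metab_processed`.
#' @export
preprocess_metabolites <- function(table, scaling = c("unit", "pareto")) {
  scaling <- match.arg(scaling)
  if (inherits(table, "metab_processed")) {
    abort("table is already preprocessed (log/scale must be applied once)")
  }
  m <- as_sample_matrix(table)
  m[m == 0] <- NA
  frac_missing <- colMeans(is.na(m))
  drop <- frac_missing >= 0.5
  if (any(drop)) {
    inform(sprintf("preprocess: dropped %d metabolites missing in >= 50%% of samples",
                   sum(drop)))
    m <- m[, !drop, drop = FALSE]
  }
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (any(miss)) m[miss, j] <- min(m[!miss, j]) / 2
  }
  if (any(m <= 0)) abort("intensities must be positive")
  lm10 <- log10(m)
  sds <- apply(lm10, 2, sd)
  if (any(sds == 0)) {
    inform(sprintf("preprocess: dropped %d constant metabolites", sum(sds == 0)))
    lm10 <- lm10[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  centered <- sweep(lm10, 2, colMeans(lm10))
  scaled <- switch(scaling,
                   unit = sweep(centered, 2, sds, "/"),
                   pareto = sweep(centered, 2, sqrt(sds), "/"))
  out <- as_sample_tibble(scaled)
  attr(out, "metab_transform") <- list(imputation = "half-minimum",
                                       log = "log10", scaling = scaling)
  class(out) <- c("metab_processed", class(out))
  out
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lev in levels(y)) {
    ix <- which(y == lev)
    fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
  }
  fold
}

# NIPALS PLS2 on centred X, Y; returns weights W, scores T, loadings P,
# Y-loadings Q and per-component explained-Y variance ssy = q^2 * t't.
nipals_pls <- function(x, y, ncomp, tol = 1e-10, max_iter = 500) {
  e <- x; f <- y
  n <- nrow(x); p <- ncol(x)
  w_mat <- matrix(0, p, ncomp); p_mat <- matrix(0, p, ncomp)
  t_mat <- matrix(0, n, ncomp); q_mat <- matrix(0, ncol(y), ncomp)
  ssy <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    u <- f[, which.max(apply(f, 2, var)), drop = TRUE]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(e, u); w <- w / sqrt(sum(w^2))
      tt <- e %*% w
      q <- crossprod(f, tt) / sum(tt^2)
      u <- f %*% q / sum(q^2)
      if (sum((tt - t_old)^2) < tol * sum(tt^2)) break
      t_old <- tt
    }
    pp <- crossprod(e, tt) / sum(tt^2)
    e <- e - tt %*% t(pp)
    ssy[a] <- sum((tt %*% t(q))^2)
    f <- f - tt %*% t(q)
    w_mat[, a] <- w; p_mat[, a] <- pp
    t_mat[, a] <- tt; q_mat[, a] <- q
  }
  list(w = w_mat, p = p_mat, t = t_mat, q = q_mat, ssy = ssy)
}

pls_coef <- function(fit) {
  # regression coefficients B with Yhat = Xc %*% B
  fit$w %*% solve(crossprod(fit$p, fit$w)) %*% t(fit$q)
}

pls_r2_q2 <- function(x, y01, ncomp, folds) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y01, 2, colMeans(y01))
  fit <- nipals_pls(xc, yc, ncomp)
  r2 <- 1 - sum((yc - fit$t %*% t(fit$q))^2) / sum(yc^2)
  press <- 0; tss <- 0
  for (k in sort(unique(folds))) {
    tr <- folds != k
    xm <- colMeans(x[tr, , drop = FALSE]); ym <- colMeans(y01[tr, , drop = FALSE])
    f <- nipals_pls(sweep(x[tr, , drop = FALSE], 2, xm),
                    sweep(y01[tr, , drop = FALSE], 2, ym), ncomp)
    yhat <- sweep(sweep(x[!tr, , drop = FALSE], 2, xm) %*% pls_coef(f), 2, ym, "+")
    press <- press + sum((y01[!tr, , drop = FALSE] - yhat)^2)
    tss <- tss + sum(sweep(y01[!tr, , drop = FALSE], 2, ym)^2)
  }
  list(fit = fit, r2 = r2, q2 = 1 - press / tss)
}

#' Fit a PLS-DA model with VIP scores and permutation validation
#'
#' NIPALS partial least squares on one-hot class indicators. Reports R2
#' (explained class variance), Q2 (`1 - PRESS/TSS` from seeded stratified
#' k-fold cross-validation), per-metabolite VIP scores
#' `VIP_j = sqrt(p * sum_a ssy_a w_aj^2 / sum_a ssy_a)` (mean VIP^2 equals 1
#' by construction), and null distributions of R2/Q2 from label
#' permutations.
#'
#' @param x processed metabolite sample table (see
#'   [preprocess_metabolites()]).
#' @param y class labels (2 or more classes) aligned with samples.
#' @param n_components number of PLS components (default 2).
#' @param cv_folds cross-validation folds for Q2 (default 7, stratified).
#' @param n_perm label permutations for the null distributions (default 999;
#'   0 skips them).
#' @param seed integer seed controlling folds and permutations.
#' @return object of class `plsda_fit`: `scores` (tibble), `vip` (tibble),
#'   `r2`, `q2`, `permutation` (tibble of null R2/Q2), component detail.
#' @export
plsda_fit <- function(x, y, n_components = 2, cv_folds = 7, n_perm = 999,
                      seed = 1) {
  m <- as_sample_matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) abort("need at least 2 classes")
  if (length(y) != nrow(m)) abort("labels must align with samples")
  if (n_components > min(dim(m))) abort("`n_components` exceeds the data rank")
  if (min(table(y)) < cv_folds) {
    abort("a cross-validation fold would miss a class; lower `cv_folds`")
  }
  y01 <- stats::model.matrix(~ y - 1)
  colnames(y01) <- levels(y)

  set.seed(seed)
  folds <- stratified_folds(y, cv_folds)
  main <- pls_r2_q2(m, y01, n_components, folds)
  fit <- main$fit

  pfeat <- ncol(m)
  wnorm <- sweep(fit$w, 2, sqrt(colSums(fit$w^2)), "/")
  vip <- sqrt(pfeat * as.numeric(wnorm^2 %*% fit$ssy) / sum(fit$ssy))

  permutation <- NULL
  if (n_perm > 0) {
    permutation <- purrr::map_dfr(seq_len(n_perm), function(i) {
      yp <- sample(y)
      yp01 <- stats::model.matrix(~ yp - 1)
      fp <- stratified_folds(yp, cv_folds)
      r <- pls_r2_q2(m, yp01, n_components, fp)
      tibble(perm = i, r2 = r$r2, q2 = r$q2)
    })
  }

  scores <- as_tibble(as.data.frame(fit$t))
  names(scores) <- paste0("Comp", seq_len(n_components))
  new_result(list(
    scores = dplyr::bind_cols(tibble(sample_id = rownames(m), class = y), scores),
    vip = tibble(metabolite_id = colnames(m), vip = vip),
    weights = fit$w, loadings = fit$p, y_loadings = fit$q, ssy = fit$ssy,
    r2 = main$r2, q2 = main$q2, permutation = permutation,
    n_components = n_components, cv_folds = cv_folds, seed = seed,
    classes = levels(y)
  ), "plsda_fit")
}

#' @export
print.plsda_fit <- function(x, ...) {
  cat(sprintf("<plsda_fit> %d components, classes: %s\n", x$n_components,
              paste(x$classes, collapse = "/")))
  cat(sprintf("  R2 = %.3f, Q2 = %.3f (%d-fold CV)\n", x$r2, x$q2, x$cv_folds))
  if (!is.null(x$permutation)) {
    cat(sprintf("  permutation null (n=%d): R2 %.3f, Q2 %.3f\n",
                nrow(x$permutation), mean(x$permutation$r2),
                mean(x$permutation$q2)))
  }
  invisible(x)
}

#' Select differential metabolites by VIP and univariate significance
#'
#' A metabolite is selected when its VIP is strictly greater than
#' `vip_threshold` AND its two-sided Wilcoxon rank-sum p-value (on raw
#' intensities) is below `p_threshold`. Fold change is the ratio of group
#' means on the raw scale (non-reference over reference); BH q-values are
#' reported alongside.
#'
#' @param model a fitted [plsda_fit()].
#' @param x_raw raw (untransformed) intensity sample table.
#' @param y two-level class labels; first level is the reference.
#' @param vip_threshold strict VIP cutoff (default 1).
#' @param p_threshold Wilcoxon p cutoff (default 0.05).
#' @return tibble: `metabolite_id`, `vip`, `p_value`, `q_value`,
#'   `fold_change`, `log2fc`, `direction`, `selected`.
#' @export
select_differential_metabolites <- function(model, x_raw, y,
                                            vip_threshold = 1,
                                            p_threshold = 0.05) {
  m <- as_sample_matrix(x_raw)
  g <- check_two_groups(y)
  ref <- levels(g)[1]
  common <- intersect(model$vip$metabolite_id, colnames(m))
  res <- purrr::map_dfr(common, function(met) {
    a <- m[g != ref, met]; b <- m[g == ref, met]
    p <- suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
    fc <- mean(a) / mean(b)
    tibble(metabolite_id = met, p_value = p, fold_change = fc,
           log2fc = log2(fc))
  })
  res <- left_join(model$vip, res, by = "metabolite_id") |>
    filter(!is.na(.data$p_value))
  res$q_value <- bh_adjust(res$p_value)
  res$direction <- ifelse(res$fold_change > 1, "elevated", "suppressed")
  res$selected <- res$vip > vip_threshold & res$p_value < p_threshold
  res[, c("metabolite_id", "vip", "p_value", "q_value", "fold_change",
          "log2fc", "direction", "selected")]
}

# WGCNA-style signed scale-free topology fit index for one power
scale_free_fit <- function(adj, n_bins = 10) {
  k <- colSums(adj)
  if (max(k) == 0) return(0)
  bins <- cut(k, breaks = n_bins)
  dk <- tapply(k, bins, mean)
  pk <- tapply(k, bins, length) / length(k)
  ok <- !is.na(dk) & dk > 0 & pk > 0
  if (sum(ok) < 3) return(0)
  fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
  -sign(coef(fit)[2]) * summary(fit)$r.squared
}

#' Detect metabolite co-abundance modules (TOM clustering)
#'
#' Unsigned weighted-correlation-network pipeline: adjacency
#' `a_ij = |cor(x_i, x_j)|^beta` with the soft-threshold power chosen as the
#' smallest integer reaching scale-free fit R2 >= `rsq_target` (falling back,
#' with a flag, to the best-fitting power); topological overlap similarity;
#' average-linkage clustering of `1 - TOM`; a static cut at `cut_height`;
#' modules smaller than `min_module_size` pooled into `"unassigned"`. Each
#' module's eigen-metabolite is the first principal component of its
#' standardised members, scaled to unit variance and sign-aligned to have
#' positive mean correlation with the members.
#'
#' @param x processed metabolite sample table.
#' @param beta soft-threshold power; `NULL` (default) selects it
#'   automatically over 1..12.
#' @param min_module_size smallest retained module (default 5).
#' @param cut_height static cut height on the `1 - TOM` dendrogram
#'   (default 0.99).
#' @param rsq_target scale-free fit target (default 0.8).
#' @return object of class `module_set`: `map` (tibble `metabolite_id`,
#'   `module`), `eigen` (sample table of eigen-metabolites), `beta`,
#'   `scale_free_r2`, `beta_flagged`.
#' @export
detect_modules <- function(x, beta = NULL, min_module_size = 5,
                           cut_height = 0.99, rsq_target = 0.8) {
  m <- as_sample_matrix(x)
  if (ncol(m) < 2 * min_module_size) {
    abort("too few metabolites for module detection")
  }
  m <- m[, order(colnames(m)), drop = FALSE]  # input-order invariance
  cc <- abs(cor(m))
  diag(cc) <- 0

  beta_flagged <- FALSE
  if (is.null(beta)) {
    fits <- vapply(1:12, function(b) scale_free_fit(cc^b), numeric(1))
    hit <- which(fits >= rsq_target)
    if (length(hit)) {
      beta <- hit[1]
    } else {
      # block-structured (non-scale-free) data never reaches the target;
      # fall back to the standard unsigned soft-threshold power
      beta <- 6
      beta_flagged <- TRUE
      inform(sprintf("no power reached scale-free fit %.2f (best %.2f); falling back to beta = 6",
                     rsq_target, max(fits)))
    }
  }
  adj <- cc^beta
  r2 <- scale_free_fit(adj)

  k <- colSums(adj)
  l <- adj %*% adj
  tom <- (l + adj) / (outer(k, k, pmin) + 1 - adj)
  diag(tom) <- 1
  hc <- hclust(as.dist(1 - tom), method = "average")
  raw <- cutree(hc, h = cut_height)

  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  # label modules by decreasing size; everything else is "unassigned"
  keep <- keep[order(-sizes[keep])]
  module <- rep("unassigned", ncol(m))
  for (i in seq_along(keep)) {
    module[raw == as.integer(keep[i])] <- sprintf("M%d", i)
  }
  map <- tibble(metabolite_id = colnames(m), module = module)

  mods <- sprintf("M%d", seq_along(keep))
  eig <- vapply(mods, function(md) {
    sub <- scale(m[, map$metabolite_id[map$module == md], drop = FALSE])
    pc1 <- prcomp(sub, center = FALSE, scale. = FALSE)$x[, 1]
    pc1 <- pc1 / sd(pc1)
    if (mean(cor(pc1, sub)) < 0) pc1 <- -pc1
    pc1
  }, numeric(nrow(m)))
  rownames(eig) <- rownames(m)

  new_result(list(map = map, eigen = as_sample_tibble(eig), beta = beta,
                  scale_free_r2 = r2, beta_flagged = beta_flagged,
                  cut_height = cut_height, tree = hc),
             "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  tab <- table(x$map$module)
  cat(sprintf("<module_set> %d metabolites, %d modules (beta = %d, scale-free R2 = %.2f%s)\n",
              nrow(x$map), sum(names(tab) != "unassigned"), x$beta,
              x$scale_free_r2, if (x$beta_flagged) ", flagged" else ""))
  cat("  sizes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Hypergeometric pathway enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a selected
#' metabolite set and each annotated pathway, with BH correction and the
#' rich factor (hits over pathway size within the universe).
#'
#' @param selected character vector of selected metabolite ids (must be a
#'   subset of `universe`).
#' @param annotation tibble with `metabolite_id` and `pathway` columns.
#' @param universe background metabolite ids; defaults to all annotated
#'   metabolites.
#' @return tibble: `pathway`, `hits`, `pathway_size`, `selected_size`,
#'   `universe_size`, `p_value`, `q_value`, `rich_factor`, sorted by p.
#' @export
pathway_enrichment <- function(selected, annotation,
                               universe = unique(annotation$metabolite_id)) {
  if (!all(selected %in% universe)) {
    abort("`selected` must be a subset of `universe`")
  }
  unannotated <- setdiff(universe, annotation$metabolite_id)
  if (length(unannotated)) {
    inform(sprintf("pathway_enrichment: %d universe metabolites unannotated (ignored)",
                   length(unannotated)))
    universe <- setdiff(universe, unannotated)
    selected <- setdiff(selected, unannotated)
  }
  if (!length(selected)) {
    inform("pathway_enrichment: empty selected set")
    return(tibble(pathway = character(), hits = integer(),
                  pathway_size = integer(), selected_size = integer(),
                  universe_size = integer(), p_value = numeric(),
                  q_value = numeric(), rich_factor = numeric()))
  }
  ann <- annotation[annotation$metabolite_id %in% universe, ]
  n_u <- length(universe); n_s <- length(selected)
  res <- purrr::map_dfr(split(ann$metabolite_id, ann$pathway), function(mem) {
    k <- length(intersect(mem, selected))
    tibble(hits = k, pathway_size = length(mem),
           p_value = phyper(k - 1, length(mem), n_u - length(mem), n_s,
                            lower.tail = FALSE),
           rich_factor = k / length(mem))
  }, .id = "pathway")
  res$selected_size <- n_s
  res$universe_size <- n_u
  res$q_value <- bh_adjust(res$p_value)
  arrange(res[, c("pathway", "hits", "pathway_size", "selected_size",
                  "universe_size", "p_value", "q_value", "rich_factor")],
          .data$p_value)
}
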