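#' Filter OTUs by total count and prevalence
#'
#' Retains OTUs whose cohort-wide total count is at least `min_total` AND
#' whose prevalence (fraction of samples with a nonzero count) is at least
#' `min_prevalence`. Column order is preserved.
#'
#' @param counts sample table of OTU counts.
#' @param min_total minimum summed count across the whole cohort (default
#'   1000).
#' @param min_prevalence minimum fraction of samples carrying the OTU
#'   (default 0.2).
#' @return filtered sample table.
#' @export
filter_otus <- function(counts, min_total = 1000, min_prevalence = 0.2) {
  m <- as_sample_matrix(counts)
  keep <- colSums(m) >= min_total & colMeans(m > 0) >= min_prevalence
  if (!any(keep)) {
    abort("no OTUs pass the filter; lower `min_total` or `min_prevalence`")
  }
  inform(sprintf("filter_otus: retained %d of %d OTUs (total >= %g, prevalence >= %g)",
                 sum(keep), ncol(m), min_total, min_prevalence))
  counts[, c(TRUE, keep), drop = FALSE]
}

# one SparCC pass: log-fraction covariance -> basis variances -> correlations,
# with iterative exclusion of the most strongly correlated pairs.
sparcc_basis <- function(logf, exclusion_threshold = 0.1, n_exclusions = 10) {
  p <- ncol(logf)
  cl <- cov(logf)
  v <- diag(cl)
  tmat <- outer(v, v, "+") - 2 * cl  # log-ratio variances t_ij
  mmat <- matrix(1, p, p)
  diag(mmat) <- p - 1
  tvec <- rowSums(tmat)
  excluded <- matrix(FALSE, p, p)

  solve_rho <- function() {
    omega <- solve(mmat, tvec)
    omega <- pmax(omega, 1e-8)
    rho <- (outer(omega, omega, "+") - tmat) / (2 * sqrt(outer(omega, omega)))
    diag(rho) <- 1
    list(rho = pmin(pmax(rho, -1), 1), omega = omega)
  }

  fit <- solve_rho()
  converged <- TRUE
  for (it in seq_len(n_exclusions)) {
    cand <- abs(fit$rho)
    cand[excluded | row(cand) >= col(cand)] <- 0
    mx <- which.max(cand)
    if (cand[mx] <= exclusion_threshold) { converged <- TRUE; break }
    i <- row(cand)[mx]; j <- col(cand)[mx]
    excluded[i, j] <- excluded[j, i] <- TRUE
    mmat[i, j] <- mmat[j, i] <- 0
    mmat[i, i] <- mmat[i, i] - 1
    mmat[j, j] <- mmat[j, j] - 1
    tvec[i] <- tvec[i] - tmat[i, j]
    tvec[j] <- tvec[j] - tmat[i, j]
    fit <- solve_rho()
    converged <- it < n_exclusions
  }
  list(rho = fit$rho, omega = fit$omega, excluded = excluded,
       converged = converged)
}

#' SparCC compositional correlation
#'
#' Estimates correlations among the (unobserved) basis abundances underlying
#' compositional count data. Counts are converted to fractions by Dirichlet
#' resampling with a 0.5 pseudocount; per resample, log-ratio variances
#' `t_ij = var(log(x_i/x_j))` feed the sparse-correlation linear system for
#' basis variances `omega`, giving
#' `rho_ij = (omega_i + omega_j - t_ij) / (2*sqrt(omega_i*omega_j))`, with
#' iterative exclusion of the most correlated pairs above
#' `exclusion_threshold`. The reported matrix is the element-wise median over
#' resamples. Pseudo p-values come from null resamples in which each OTU
#' column is permuted independently across samples.
#'
#' @param counts sample table of OTU counts (at least 4 OTUs).
#' @param n_iter Dirichlet resampling iterations (default 20); `n_iter = 1`
#'   uses deterministic point-estimate fractions instead of resampling.
#' @param exclusion_threshold correlation magnitude above which the single
#'   strongest pair is excluded from the basis system each round.
#' @param n_exclusions maximum exclusion rounds per iteration (default 10).
#' @param n_bootstraps null resamples for pseudo p-values; 0 skips them.
#' @param seed integer seed (mandatory; the estimator is resampling-based).
#' @return object of class `sparcc_fit`: `rho` (correlation matrix),
#'   `omega` (basis variances), `p_value` (matrix or NULL), `n_excluded`,
#'   `converged`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_otus = 30, n_guilds = 3, seed = 2))
#' fit <- sparcc(coh$counts, n_iter = 5, n_bootstraps = 0, seed = 1)
#' fit$rho[1:3, 1:3]
#' @export
sparcc <- function(counts, n_iter = 20, exclusion_threshold = 0.1,
                   n_exclusions = 10, n_bootstraps = 100, seed) {
  if (missing(seed)) abort("`seed` is mandatory for sparcc()")
  m <- as_sample_matrix(counts)
  if (ncol(m) < 4) abort("sparcc needs at least 4 OTUs")
  set.seed(seed)
  p <- ncol(m)

  draw_fracs <- function(mm) {
    if (n_iter == 1) {
      # point-estimate fractions: deterministic, sample-order invariant
      f <- mm + 0.5
      return(f / rowSums(f))
    }
    # one Dirichlet(counts + 0.5) draw per sample
    g <- matrix(stats::rgamma(length(mm), shape = mm + 0.5), nrow(mm), ncol(mm))
    g / rowSums(g)
  }

  rhos <- array(NA_real_, c(p, p, n_iter))
  omegas <- matrix(NA_real_, p, n_iter)
  conv <- logical(n_iter)
  excl <- matrix(FALSE, p, p)
  for (it in seq_len(n_iter)) {
    fit <- sparcc_basis(log(draw_fracs(m)), exclusion_threshold, n_exclusions)
    rhos[, , it] <- fit$rho
    omegas[, it] <- fit$omega
    conv[it] <- fit$converged
    excl <- excl | fit$excluded
  }
  rho <- apply(rhos, c(1, 2), median)
  dimnames(rho) <- list(colnames(m), colnames(m))
  diag(rho) <- 1

  p_value <- NULL
  if (n_bootstraps > 0) {
    exceed <- matrix(0, p, p)
    for (b in seq_len(n_bootstraps)) {
      null_m <- apply(m, 2, sample)
      null_fit <- sparcc_basis(log(draw_fracs(null_m)),
                               exclusion_threshold, n_exclusions)
      exceed <- exceed + (abs(null_fit$rho) >= abs(rho))
    }
    p_value <- (1 + exceed) / (n_bootstraps + 1)
    diag(p_value) <- 0
    dimnames(p_value) <- dimnames(rho)
  }

  if (!all(conv)) {
    inform(sprintf("sparcc: exclusion did not converge in %d of %d iterations; last iterates used",
                 sum(!conv), n_iter))
  }
  new_result(list(rho = rho,
                  omega = setNames(rowMeans(omegas), colnames(m)),
                  p_value = p_value,
                  n_excluded = sum(excl) / 2,
                  converged = all(conv)),
             "sparcc_fit")
}

#' @export
print.sparcc_fit <- function(x, ...) {
  off <- x$rho[lower.tri(x$rho)]
  cat(sprintf("<sparcc_fit> %d OTUs; mean |rho| %.3f; %d pairs excluded; %s\n",
              ncol(x$rho), mean(abs(off)), x$n_excluded,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Cluster OTUs into co-abundance groups (CAGs)
#'
#' Hierarchical clustering of the SparCC correlation matrix on the
#' dissimilarity `1 - rho` (Ward linkage by default). The partition is cut
#' either at a requested number of groups or at a dendrogram height; OTUs are
#' ordered by id before clustering so the result does not depend on input
#' order.
#'
#' @param fit a [sparcc()] result (or any list with a `rho` matrix).
#' @param n_cags number of co-abundance groups to cut (default 19).
#' @param cut_height alternative: cut the dendrogram at this height.
#' @param method linkage passed to [stats::hclust()] (default `"ward.D2"`).
#' @return object of class `cag_partition`: tibble `map` (`otu_id`, `cag`),
#'   the `hclust` tree, and member lists.
#' @export
cluster_cags <- function(fit, n_cags = 19, cut_height = NULL,
                         method = "ward.D2") {
  rho <- fit$rho
  ord <- order(colnames(rho))
  rho <- rho[ord, ord]
  if (!is.null(n_cags) && is.null(cut_height) && n_cags > ncol(rho)) {
    abort("`n_cags` exceeds the number of OTUs")
  }
  hc <- hclust(as.dist(1 - rho), method = method)
  raw <- if (!is.null(cut_height)) cutree(hc, h = cut_height) else cutree(hc, k = n_cags)
  # relabel so CAG ids follow first appearance in OTU-id order
  lev <- unique(raw[order(names(raw))])
  cag <- match(raw, lev)
  map <- tibble(otu_id = names(raw),
                cag = sprintf("CAG%d", cag)) |> arrange(.data$otu_id)
  new_result(list(map = map, tree = hc,
                  members = split(map$otu_id, map$cag)),
             "cag_partition")
}

#' @export
print.cag_partition <- function(x, ...) {
  sizes <- vapply(x$members, length, integer(1))
  cat(sprintf("<cag_partition> %d OTUs in %d CAGs (sizes %d-%d)\n",
              nrow(x$map), length(x$members), min(sizes), max(sizes)))
  invisible(x)
}

#' Per-sample CAG abundances and Z-scores
#'
#' CAG abundance is the summed relative abundance of member OTUs; since the
#' partition is exhaustive, the abundances sum to one per sample. Z-scores
#' standardise each CAG across samples (zero mean, unit sd); CAGs with zero
#' variance get all-zero Z rows and are flagged.
#'
#' @param counts sample table of (retained) OTU counts.
#' @param partition a [cluster_cags()] result.
#' @return object of class `cag_abundance` with `abundance` and `zscore`
#'   sample tables and `constant_cags` (character vector of flagged CAGs).
#' @export
cag_abundance <- function(counts, partition) {
  rel <- as_sample_matrix(relative_abundance(counts))
  map <- partition$map
  missing <- setdiff(map$otu_id, colnames(rel))
  if (length(missing)) {
    abort(paste0("partition OTUs absent from counts: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  cags <- sort(unique(map$cag))
  ab <- vapply(cags, function(cg) {
    rowSums(rel[, map$otu_id[map$cag == cg], drop = FALSE])
  }, numeric(nrow(rel)))
  # sample-size (n-1) sd convention, as in scale()
  sds <- apply(ab, 2, sd)
  constant <- cags[sds == 0]
  z <- scale(ab)
  z[, sds == 0] <- 0
  if (length(constant)) {
    warn(paste0("constant CAG abundance, Z set to 0: ",
                paste(constant, collapse = ", ")))
  }
  new_result(list(abundance = as_sample_tibble(ab),
                  zscore = as_sample_tibble(z),
                  constant_cags = constant),
             "cag_abundance")
}

#' Wilcoxon rank-sum tests of CAG abundance between two groups
#'
#' Two-sided Wilcoxon rank-sum test per CAG (exact distribution when both
#' groups have at most 25 samples and no ties; normal approximation with tie
#' correction otherwise). Direction is the sign of the median difference in
#' the non-reference group relative to the first factor level.
#'
#' @param cag_ab a [cag_abundance()] result (its `abundance` table is used)
#'   or any sample table.
#' @param groups two-level grouping aligned with the samples; the first
#'   factor level is the reference (e.g. controls).
#' @return tibble with per-CAG `statistic` (W), `p_value`, `q_value` (BH),
#'   `median_diff`, `direction`, `flag`.
#' @export
test_cag_differences <- function(cag_ab, groups) {
  tab <- if (inherits(cag_ab, "cag_abundance")) cag_ab$abundance else cag_ab
  m <- as_sample_matrix(tab)
  g <- check_two_groups(groups)
  ref <- levels(g)[1]
  res <- purrr::map_dfr(colnames(m), function(cg) {
    x <- m[g != ref, cg]  # non-reference (e.g. patients)
    y <- m[g == ref, cg]
    if (length(unique(c(x, y))) == 1) {
      return(tibble(feature = cg, statistic = NA_real_, p_value = 1,
                    median_diff = 0, direction = "none", flag = "all tied"))
    }
    exact <- max(length(x), length(y)) <= 25
    wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
    md <- median(x) - median(y)
    tibble(feature = cg, statistic = unname(wt$statistic),
           p_value = wt$p.value, median_diff = md,
           direction = if (md > 0) "increased" else if (md < 0) "decreased" else "none",
           flag = NA_character_)
  })
  res$q_value <- bh_adjust(res$p_value)
  res[, c("feature", "statistic", "p_value", "q_value", "median_diff",
          "direction", "flag")]
}
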