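#' Aggregate OTU counts to genus level
#'
#' @param counts sample table of OTU counts.
#' @param taxonomy tibble with `otu_id` and `genus`.
#' @return sample table of per-genus summed counts.
#' @export
aggregate_genus <- function(counts, taxonomy) {
  m <- as_sample_matrix(counts)
  tax <- taxonomy[match(colnames(m), taxonomy$otu_id), ]
  if (anyNA(tax$genus)) abort("taxonomy does not cover all OTUs")
  genera <- sort(unique(tax$genus))
  out <- vapply(genera, function(gn) {
    rowSums(m[, tax$otu_id[tax$genus == gn], drop = FALSE])
  }, numeric(nrow(m)))
  as_sample_tibble(out)
}

#' Welch t-tests of cytokine levels between two groups
#'
#' Two-sided Welch t-test per cytokine on log10-transformed concentrations
#' (cytokine panels are right-skewed); direction is the sign of the mean
#' difference in the non-reference group.
#'
#' @param cytokines sample table of cytokine concentrations (pg/ml).
#' @param groups two-level grouping aligned with samples; first level is the
#'   reference.
#' @param log_transform log10-transform before testing (default TRUE).
#' @return tibble: `cytokine`, `statistic` (t), `p_value`, `q_value`,
#'   `mean_diff` (log scale), `direction`, `flag`.
#' @export
cytokine_group_tests <- function(cytokines, groups, log_transform = TRUE) {
  m <- as_sample_matrix(cytokines)
  if (any(m < 0)) abort("cytokine concentrations must be non-negative")
  g <- check_two_groups(groups)
  ref <- levels(g)[1]
  if (log_transform) m <- log10(m + min(m[m > 0]) / 2)
  res <- purrr::map_dfr(colnames(m), function(ck) {
    a <- m[g != ref, ck]; b <- m[g == ref, ck]
    if (sd(a) == 0 && sd(b) == 0) {
      return(tibble(cytokine = ck, statistic = NA_real_, p_value = NA_real_,
                    mean_diff = mean(a) - mean(b), direction = "none",
                    flag = "zero variance"))
    }
    tt <- t.test(a, b)
    md <- mean(a) - mean(b)
    tibble(cytokine = ck, statistic = unname(tt$statistic),
           p_value = tt$p.value, mean_diff = md,
           direction = if (md > 0) "elevated" else "suppressed",
           flag = NA_character_)
  })
  res$q_value <- NA_real_
  ok <- !is.na(res$p_value)
  res$q_value[ok] <- bh_adjust(res$p_value[ok])
  res[, c("cytokine", "statistic", "p_value", "q_value", "mean_diff",
          "direction", "flag")]
}

p_stars <- function(p) {
  dplyr::case_when(p < 1e-4 ~ "****", p < 1e-3 ~ "***", p < 1e-2 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "")
}

#' Genus-cytokine Spearman correlation grid
#'
#' All pairwise Spearman correlations between the `top_n` most differential
#' genera (ranked by Wilcoxon p between groups, or by variance when no
#' groups are given) and the cytokines, with significance stars at
#' p < 0.05 / 0.01 / 0.001 / 0.0001.
#'
#' @param genus sample table of genus relative abundances (or counts).
#' @param cytokines sample table of cytokine concentrations; samples are
#'   inner-joined with `genus`.
#' @param groups optional two-level grouping used to rank genera.
#' @param top_n how many genera to keep (default 30).
#' @return tibble edge list: `genus`, `cytokine`, `rho`, `p_value`, `stars`.
#' @export
genus_cytokine_correlations <- function(genus, cytokines, groups = NULL,
                                        top_n = 30) {
  gm <- as_sample_matrix(genus)
  cm <- as_sample_matrix(cytokines)
  shared <- intersect(rownames(gm), rownames(cm))
  if (length(shared) < 3) abort("fewer than 3 shared samples")
  if (!is.null(groups)) {
    if (!is.null(names(groups))) groups <- groups[rownames(gm)]
    g <- check_two_groups(groups)
    pvals <- apply(gm, 2, function(col) {
      suppressWarnings(wilcox.test(col[g == levels(g)[1]],
                                   col[g != levels(g)[1]], exact = FALSE)$p.value)
    })
    keep <- names(sort(pvals))[seq_len(min(top_n, ncol(gm)))]
  } else {
    keep <- names(sort(apply(gm, 2, var), decreasing = TRUE))[seq_len(min(top_n, ncol(gm)))]
  }
  sp <- spearman_matrix(gm[shared, keep, drop = FALSE],
                        cm[shared, , drop = FALSE])
  out <- tidyr::expand_grid(genus = keep, cytokine = colnames(cm))
  out$rho <- as.numeric(t(sp$rho))
  out$p_value <- as.numeric(t(sp$p))
  out$stars <- p_stars(out$p_value)
  arrange(out, .data$genus, .data$cytokine)
}

#' FDR-controlled cross-omic Spearman network
#'
#' Spearman correlations across CAG abundances, fecal and serum
#' eigen-metabolites and cytokines, computed over the shared sample subset
#' of each table pair. BH correction is applied within each pair family
#' (CAG x fecal modules, CAG x serum modules, modules x cytokines, and
#' optionally CAG x cytokines) or pooled; edges with `q < fdr` form the
#' significant view.
#'
#' @param cag sample table of CAG abundances.
#' @param fecal_eigen,serum_eigen sample tables of eigen-metabolites (either
#'   may be NULL).
#' @param cytokines sample table of cytokine concentrations (may be NULL).
#' @param fdr BH q-value threshold for the significant view (default 0.05).
#' @param include_cag_cytokine also compute direct CAG-cytokine edges
#'   (default TRUE; they form their own family).
#' @param pool_families apply BH across all families at once instead of
#'   within family (default FALSE).
#' @param min_overlap smallest allowed shared-sample count per pair family.
#' @return object of class `omic_network`: tibble `edges` (`node_a`,
#'   `node_b`, `family`, `rho`, `p_value`, `q_value`, `sign`, `n`,
#'   `significant`) plus the threshold used.
#' @export
build_integration_network <- function(cag, fecal_eigen = NULL,
                                      serum_eigen = NULL, cytokines = NULL,
                                      fdr = 0.05,
                                      include_cag_cytokine = TRUE,
                                      pool_families = FALSE,
                                      min_overlap = 10) {
  tabs <- list(cag = cag, fecal_module = fecal_eigen,
               serum_module = serum_eigen, cytokine = cytokines)
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  mats <- lapply(tabs, as_sample_matrix)

  pair_family <- function(a, b) {
    shared <- intersect(rownames(mats[[a]]), rownames(mats[[b]]))
    if (length(shared) < min_overlap) {
      abort(sprintf("only %d shared samples between %s and %s (need >= %d)",
                    length(shared), a, b, min_overlap))
    }
    sp <- spearman_matrix(mats[[a]][shared, , drop = FALSE],
                          mats[[b]][shared, , drop = FALSE])
    grid <- tidyr::expand_grid(node_a = colnames(mats[[a]]),
                               node_b = colnames(mats[[b]]))
    grid$rho <- as.numeric(t(sp$rho))
    grid$p_value <- as.numeric(t(sp$p))
    grid$n <- length(shared)
    grid$family <- paste(a, b, sep = "-")
    grid$type_a <- a
    grid$type_b <- b
    grid
  }

  fams <- list()
  if ("fecal_module" %in% names(mats)) fams <- c(fams, list(pair_family("cag", "fecal_module")))
  if ("serum_module" %in% names(mats)) fams <- c(fams, list(pair_family("cag", "serum_module")))
  if ("cytokine" %in% names(mats)) {
    if ("fecal_module" %in% names(mats)) fams <- c(fams, list(pair_family("fecal_module", "cytokine")))
    if ("serum_module" %in% names(mats)) fams <- c(fams, list(pair_family("serum_module", "cytokine")))
    if (include_cag_cytokine) fams <- c(fams, list(pair_family("cag", "cytokine")))
  }
  if (!length(fams)) abort("need at least one non-CAG table")
  edges <- dplyr::bind_rows(fams)

  if (pool_families) {
    edges$q_value <- bh_adjust(edges$p_value)
  } else {
    edges <- edges |>
      group_by(.data$family) |>
      mutate(q_value = bh_adjust(.data$p_value)) |>
      ungroup()
  }
  edges$sign <- ifelse(edges$rho >= 0, "positive", "negative")
  edges$significant <- edges$q_value < fdr
  new_result(list(edges = arrange(edges, .data$q_value), fdr = fdr,
                  pooled = pool_families),
             "omic_network")
}

#' @export
print.omic_network <- function(x, ...) {
  sig <- x$edges[x$edges$significant, ]
  cat(sprintf("<omic_network> %d pairs tested, %d significant at FDR %.2g\n",
              nrow(x$edges), nrow(sig), x$fdr))
  for (fam in unique(x$edges$family)) {
    cat(sprintf("  %s: %d/%d significant\n", fam,
                sum(sig$family == fam), sum(x$edges$family == fam)))
  }
  invisible(x)
}
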