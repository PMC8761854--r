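#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a SparCC fit into an edge list
#'
#' @param x a [sparcc()] result.
#' @param threshold keep edges with `|rho|` above this magnitude (default 0,
#'   i.e. all pairs; 0.4 reproduces the usual network display cut).
#' @param ... ignored.
#' @return tibble: `otu_a`, `otu_b`, `rho`, `p_value` (if computed).
#' @export
tidy.sparcc_fit <- function(x, threshold = 0, ...) {
  ids <- colnames(x$rho)
  pairs <- which(upper.tri(x$rho), arr.ind = TRUE)
  out <- tibble(otu_a = ids[pairs[, 1]], otu_b = ids[pairs[, 2]],
                rho = x$rho[pairs])
  if (!is.null(x$p_value)) out$p_value <- x$p_value[pairs]
  out[abs(out$rho) > threshold, ]
}

#' @export
glance.sparcc_fit <- function(x, ...) {
  off <- x$rho[lower.tri(x$rho)]
  tibble(n_otus = ncol(x$rho), mean_abs_rho = mean(abs(off)),
         n_excluded = x$n_excluded, converged = x$converged)
}

#' @export
tidy.cag_partition <- function(x, ...) x$map

#' @export
tidy.plsda_fit <- function(x, ...) x$vip

#' @export
glance.plsda_fit <- function(x, ...) {
  out <- tibble(n_components = x$n_components, r2 = x$r2, q2 = x$q2,
                cv_folds = x$cv_folds)
  if (!is.null(x$permutation)) {
    out$perm_r2_null <- mean(x$permutation$r2)
    out$perm_q2_null <- mean(x$permutation$q2)
    out$perm_p_q2 <- (1 + sum(x$permutation$q2 >= x$q2)) /
      (nrow(x$permutation) + 1)
  }
  out
}

#' @export
tidy.module_set <- function(x, ...) x$map

#' @export
glance.module_set <- function(x, ...) {
  tibble(n_modules = sum(unique(x$map$module) != "unassigned"),
         n_unassigned = sum(x$map$module == "unassigned"),
         beta = x$beta, scale_free_r2 = x$scale_free_r2,
         beta_flagged = x$beta_flagged)
}

#' @export
tidy.omic_network <- function(x, significant_only = FALSE, ...) {
  if (significant_only) x$edges[x$edges$significant, ] else x$edges
}

#' @export
glance.omic_network <- function(x, ...) {
  tibble(n_tested = nrow(x$edges), n_significant = sum(x$edges$significant),
         fdr = x$fdr, pooled = x$pooled)
}

#' @export
tidy.rf_outcome <- function(x, ...) x$importance

#' @export
glance.rf_outcome <- function(x, ...) {
  tibble(auc = x$auc, auc_ci_low = x$auc_ci[1], auc_ci_high = x$auc_ci[2],
         sensitivity = x$sensitivity, specificity = x$specificity,
         scheme = x$scheme)
}

#' @export
tidy.relapse_survival <- function(x, ...) x$km

#' @export
glance.relapse_survival <- function(x, ...) {
  dplyr::bind_cols(tibble(n = x$n, n_events = x$n_events),
                   x$cox, logrank_p = x$logrank$p_value)
}

#' @export
tidy.pcoa_ord <- function(x, ...) x$scores
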