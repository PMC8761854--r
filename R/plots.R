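#' @importFrom ggplot2 ggplot aes geom_point geom_tile geom_step geom_col
#'   geom_hline geom_vline labs theme_minimal scale_fill_gradient2
#'   scale_size_continuous autoplot coord_flip
NULL

#' @export
ggplot2::autoplot

#' Ordination scatter plot
#'
#' @param object a [pcoa_ordination()] result.
#' @param groups optional grouping vector (named by sample id or aligned)
#'   used for colour.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.pcoa_ord <- function(object, groups = NULL, ...) {
  df <- object$scores
  if (!is.null(groups)) {
    df$group <- if (!is.null(names(groups))) groups[df$sample_id] else groups
  }
  ve <- object$var_explained
  p <- ggplot(df, aes(x = .data$Axis1, y = .data$Axis2)) +
    theme_minimal() +
    labs(x = sprintf("PCo1 (%.1f%%)", 100 * ve[1]),
         y = sprintf("PCo2 (%.1f%%)", 100 * ve[2]))
  if (!is.null(groups)) p + geom_point(aes(colour = .data$group)) else p + geom_point()
}

#' CAG Z-score heatmap
#'
#' Tile heatmap of per-sample CAG Z-scores (green below the mean, red
#' above), samples ordered by group when given.
#'
#' @param cag_ab a [cag_abundance()] result.
#' @param groups optional grouping (named or aligned) used to order samples.
#' @return a ggplot.
#' @export
plot_cag_heatmap <- function(cag_ab, groups = NULL) {
  z <- cag_ab$zscore
  long <- tidyr::pivot_longer(z, -"sample_id", names_to = "cag",
                              values_to = "z")
  if (!is.null(groups)) {
    g <- if (!is.null(names(groups))) groups[z$sample_id] else groups
    long$sample_id <- factor(long$sample_id, levels = z$sample_id[order(g)])
  }
  ggplot(long, aes(x = .data$sample_id, y = .data$cag, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "darkgreen", mid = "white", high = "firebrick") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
    labs(x = "sample", y = NULL, fill = "Z")
}

#' Volcano plot of differential metabolites
#'
#' @param selected result of [select_differential_metabolites()].
#' @param p_threshold horizontal significance line (default 0.05).
#' @return a ggplot.
#' @export
plot_volcano <- function(selected, p_threshold = 0.05) {
  ggplot(selected, aes(x = .data$log2fc, y = -log10(.data$p_value),
                       colour = .data$selected)) +
    geom_point(alpha = 0.7) +
    geom_hline(yintercept = -log10(p_threshold), linetype = 2) +
    geom_vline(xintercept = 0, linetype = 3) +
    theme_minimal() +
    labs(x = "log2 fold change", y = "-log10 p", colour = "selected")
}

#' Pathway enrichment dot plot
#'
#' Rich factor on the x axis, dot size = hits, colour = -log10 p; the
#' standard enrichment "bubble" display.
#'
#' @param enrichment result of [pathway_enrichment()].
#' @param p_threshold pathways below this p are emphasised (default 0.05).
#' @return a ggplot.
#' @export
plot_enrichment <- function(enrichment, p_threshold = 0.05) {
  ggplot(enrichment, aes(x = .data$rich_factor,
                         y = stats::reorder(.data$pathway, -.data$p_value),
                         size = .data$hits, colour = -log10(.data$p_value))) +
    geom_point() +
    ggplot2::scale_colour_gradient(low = "pink", high = "red") +
    theme_minimal() +
    labs(x = "rich factor", y = NULL, colour = "-log10 p", size = "hits")
}

#' ROC curve of an outcome model
#'
#' @param object an [rf_outcome_model()] result.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.rf_outcome <- function(object, ...) {
  ggplot(object$roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    theme_minimal() +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("AUC = %.2f (95%% CI %.2f-%.2f)", object$auc,
                         object$auc_ci[1], object$auc_ci[2]))
}

#' Kaplan-Meier relapse curves
#'
#' @param object a [relapse_survival()] result.
#' @param ... ignored.
#' @return a ggplot of step survival curves per stratum.
#' @export
autoplot.relapse_survival <- function(object, ...) {
  km <- object$km |>
    group_by(.data$stratum) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble(time = 0, n_risk = max(.x$n_risk), n_event = 0L, survival = 1), .x)) |>
    ungroup()
  ggplot(km, aes(x = .data$time, y = .data$survival, colour = .data$stratum)) +
    geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    theme_minimal() +
    labs(x = "months", y = "relapse-free fraction", colour = "diversity")
}

#' Bar plot of random-forest feature importance
#'
#' @param fit an [rf_outcome_model()] result.
#' @param top_n features shown (default 10).
#' @return a ggplot.
#' @export
plot_importance <- function(fit, top_n = 10) {
  df <- head(fit$importance, top_n)
  ggplot(df, aes(x = .data$mean_decrease_accuracy,
                 y = stats::reorder(.data$feature, .data$mean_decrease_accuracy))) +
    geom_col() +
    theme_minimal() +
    labs(x = "mean decrease accuracy", y = NULL)
}
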