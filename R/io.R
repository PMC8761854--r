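#' Read a feature table from TSV
#'
#' Canonical dialect: tab-delimited, UTF-8, header row, first column holds
#' ids. Orientation (samples in rows vs columns) is auto-detected when a set
#' of known sample ids is supplied; duplicated ids or non-numeric cells are
#' errors naming the offender.
#'
#' @param path TSV file path.
#' @param samples optional character vector of known sample ids used to
#'   auto-detect (and fix) a transposed table.
#' @return sample table tibble (`sample_id` first).
#' @export
read_feature_table <- function(path, samples = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) abort("expected an id column plus at least one feature")
  ids <- as.character(df[[1]])
  if (!is.null(samples)) {
    row_hit <- mean(ids %in% samples)
    col_hit <- mean(colnames(df)[-1] %in% samples)
    if (col_hit > row_hit) {
      inform(sprintf("read_feature_table: %s looks transposed; fixing orientation",
                     basename(path)))
      m <- as.matrix(df[, -1, drop = FALSE])
      rownames(m) <- ids
      df <- data.frame(sample_id = colnames(m), t(m), check.names = FALSE)
      ids <- df$sample_id
    }
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) abort(paste0("duplicated ids in ", basename(path), ": ",
                                paste(dup, collapse = ", ")))
  bad <- names(df)[-1][!vapply(df[-1], is.numeric, logical(1))]
  if (length(bad)) abort(paste0("non-numeric columns in ", basename(path), ": ",
                                paste(head(bad, 5), collapse = ", ")))
  names(df)[1] <- "sample_id"
  as_tibble(df)
}

#' @rdname read_feature_table
#' @export
read_count_table <- function(path, samples = NULL) {
  tab <- read_feature_table(path, samples)
  m <- as_sample_matrix(tab)
  if (any(m < 0) || any(m != round(m))) abort("counts must be non-negative integers")
  tab
}

#' Read clinical metadata from TSV
#'
#' @param path TSV with a `sample_id` column.
#' @return tibble, one row per participant.
#' @export
read_clinical <- function(path) {
  df <- as_tibble(utils::read.delim(path, check.names = FALSE,
                                    stringsAsFactors = FALSE))
  if (!"sample_id" %in% names(df)) names(df)[1] <- "sample_id"
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) abort(paste0("duplicated sample ids: ", paste(dup, collapse = ", ")))
  df
}

#' Read a rooted tree in newick format
#'
#' @param path newick file.
#' @param otus optional OTU ids that must all be tree leaves.
#' @return an `ape::phylo` tree.
#' @export
read_tree <- function(path, otus = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort("could not parse newick tree")
  if (!is.null(otus)) {
    missing <- setdiff(otus, tree$tip.label)
    if (length(missing)) {
      abort(paste0("tree is missing leaves: ", paste(head(missing, 5), collapse = ", ")))
    }
  }
  tree
}

#' Write a sample table to TSV
#'
#' @param table sample table tibble.
#' @param path output path.
#' @export
write_feature_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write every table of a synthetic cohort to a directory
#'
#' Emits counts, taxonomy, newick tree, fecal/serum metabolite tables,
#' annotation map, clinical table, cytokine table and a JSON ground-truth
#' summary.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "guild_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(cohort$counts, file.path(dir, "counts.tsv"))
  write_feature_table(cohort$taxonomy, file.path(dir, "taxonomy.tsv"))
  ape::write.tree(cohort$tree, file.path(dir, "tree.nwk"))
  write_feature_table(cohort$fecal, file.path(dir, "fecal_metabolites.tsv"))
  write_feature_table(cohort$serum, file.path(dir, "serum_metabolites.tsv"))
  write_feature_table(cohort$annotation, file.path(dir, "annotation.tsv"))
  write_feature_table(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_feature_table(cohort$cytokines, file.path(dir, "cytokines.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    gt <- cohort$truth
    jsonlite::write_json(list(
      otu_guild_labels = as.list(gt$otu_guild_labels),
      affected_guilds = gt$affected_guilds,
      prognostic_otus = gt$prognostic_otus,
      elevated_cytokines = gt$elevated_cytokines,
      true_relapse_groups = as.list(gt$true_relapse_groups)
    ), file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' @rdname read_feature_table
#' @export
read_metabolite_table <- function(path, samples = NULL) {
  tab <- read_feature_table(path, samples)
  m <- as_sample_matrix(tab)
  if (any(m < 0)) abort("metabolite intensities must be non-negative")
  tab
}

#' Write every table of an analysis run to a directory
#'
#' Emits the declared outputs of each stage as TSV (alpha diversity, UniFrac
#' distances, PCoA coordinates, SparCC correlations and edge list, CAG map
#' and Z-scores, differential taxa, MD-index, VIP/selection tables, module
#' maps and eigen-metabolites, enrichment, cytokine statistics, the
#' genus-cytokine grid, network edges, random-forest importances and ROC
#' points, Kaplan-Meier table) plus a JSON summary with provenance.
#'
#' @param res a [run_analysis()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_analysis <- function(res, dir) {
  stopifnot(inherits(res, "guild_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(tab, name) write_feature_table(tab, file.path(dir, name))
  w(res$ecology$alpha, "alpha_diversity.tsv")
  dm <- as.matrix(res$ecology$unifrac)
  w(as_sample_tibble(dm), "unifrac_distance.tsv")
  w(res$ecology$pcoa$scores, "pcoa_coordinates.tsv")
  w(dplyr::bind_rows(res$ecology$anosim, res$ecology$permanova),
    "community_tests.tsv")
  w(as_sample_tibble(res$guilds$sparcc$rho, id = "otu_id"), "sparcc_rho.tsv")
  w(tidy(res$guilds$sparcc, threshold = 0.4), "sparcc_edges.tsv")
  w(res$guilds$partition$map, "cag_map.tsv")
  w(res$guilds$abundance$abundance, "cag_abundance.tsv")
  w(res$guilds$abundance$zscore, "cag_zscores.tsv")
  w(res$guilds$tests, "cag_tests.tsv")
  w(res$dysbiosis$differential, "differential_taxa.tsv")
  if (!is.null(res$dysbiosis$md)) w(res$dysbiosis$md, "md_index.tsv")
  if (!is.null(res$dysbiosis$association)) {
    w(res$dysbiosis$association, "md_associations.tsv")
  }
  for (cmp in c("fecal", "serum")) {
    w(res[[cmp]]$selected, sprintf("%s_selected_metabolites.tsv", cmp))
    w(res[[cmp]]$modules$map, sprintf("%s_module_map.tsv", cmp))
    w(res[[cmp]]$modules$eigen, sprintf("%s_eigen_metabolites.tsv", cmp))
    w(res[[cmp]]$enrichment, sprintf("%s_enrichment.tsv", cmp))
  }
  w(res$integration$cytokine_tests, "cytokine_tests.tsv")
  w(res$integration$genus_cytokine, "genus_cytokine_grid.tsv")
  w(res$integration$network$edges, "network_edges.tsv")
  w(res$prognosis$rf$importance, "rf_importance.tsv")
  w(res$prognosis$rf$roc, "rf_roc.tsv")
  w(res$prognosis$survival$km, "km_curves.tsv")
  w(res$prognosis$survival$at_risk, "km_at_risk.tsv")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(list(
      provenance = res$provenance,
      rf_auc = res$prognosis$rf$auc,
      rf_auc_ci = res$prognosis$rf$auc_ci,
      sensitivity = res$prognosis$rf$sensitivity,
      specificity = res$prognosis$rf$specificity,
      adjusted_or = as.list(res$prognosis$adjusted_or),
      cox = as.list(res$prognosis$survival$cox),
      logrank = as.list(res$prognosis$survival$logrank)
    ), file.path(dir, "report.json"), auto_unbox = TRUE, na = "null",
    digits = NA)
  }
  invisible(dir)
}
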