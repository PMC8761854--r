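#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange left_join inner_join bind_rows group_by summarise ungroup
#' @importFrom tibble tibble as_tibble
#' @importFrom stats cor cov cor.test sd var median quantile rnorm runif rbinom rexp rmultinom rlnorm p.adjust pt phyper plogis qnorm pnorm setNames prcomp cutree hclust as.dist dist wilcox.test t.test glm binomial coef vcov uniroot complete.cases
#' @importFrom utils head combn
NULL

# A "sample table" is a tibble whose first column is `sample_id` and whose
# remaining columns are numeric features (OTUs, metabolites, cytokines, CAGs).

#' Convert a sample table to a numeric matrix
#'
#' @param df data frame with a `sample_id` first column and numeric features.
#' @return numeric matrix, samples in rows (rownames = sample ids).
#' @keywords internal
#' @noRd
as_sample_matrix <- function(df) {
  df <- as.data.frame(df)
  id_col <- names(df)[1]
  if (!id_col %in% c("sample_id", "id", "sample")) {
    # accept any first column of character/factor ids
    if (is.numeric(df[[1]])) {
      abort("first column must hold sample identifiers (got numeric)")
    }
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated sample ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("feature columns must be numeric")
  rownames(m) <- ids
  m
}

as_sample_tibble <- function(m, id = "sample_id") {
  out <- as_tibble(as.data.frame(m, check.names = FALSE))
  out <- dplyr::bind_cols(tibble(!!id := rownames(m)), out)
  out
}

#' Per-sample relative abundances
#'
#' Divides each sample's counts by its total. Samples with zero total are
#' rejected.
#'
#' @param counts sample table of non-negative counts.
#' @param pseudocount value added to every cell before closure (default 0,
#'   i.e. plain proportions).
#' @return sample table of proportions summing to one per sample.
#' @export
relative_abundance <- function(counts, pseudocount = 0) {
  m <- as_sample_matrix(counts)
  if (any(m < 0)) abort("counts must be non-negative")
  m <- m + pseudocount
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    abort(paste0("samples with zero total counts: ",
                 paste(rownames(m)[tot <= 0], collapse = ", ")))
  }
  as_sample_tibble(m / tot)
}

# Benjamini-Hochberg step-up q-values; thin wrapper kept so the network and
# differential modules share one code path.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

# midrank-based Spearman rho for two matrices (columns of x vs columns of y),
# with t-approximation p-values; the scalar spearman_test() handles exact
# small-n p separately.
spearman_matrix <- function(x, y) {
  rx <- apply(x, 2, rank)
  ry <- apply(y, 2, rank)
  n <- nrow(x)
  rho <- suppressWarnings(stats::cor(rx, ry))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(rho) >= 1] <- 0
  list(rho = rho, p = p, n = n)
}

check_two_groups <- function(groups) {
  g <- as.factor(groups)
  if (nlevels(droplevels(g)) != 2) abort("exactly two groups are required")
  droplevels(g)
}

new_result <- function(x, class, ...) {
  structure(x, class = c(class, class(x)), ...)
}
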