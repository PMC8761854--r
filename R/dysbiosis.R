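#' Median-of-ratios size factors
#'
#' DESeq-style normalisation: each sample's size factor is the median across
#' features of its count divided by the feature's geometric mean, using only
#' features positive in every sample. Falls back to total-count scaling when
#' no feature is always positive.
#'
#' @param counts sample table of counts.
#' @return named numeric vector of size factors (geometric mean 1).
#' @export
size_factors <- function(counts) {
  m <- as_sample_matrix(counts)
  always_pos <- colSums(m == 0) == 0
  if (any(always_pos)) {
    lm <- log(m[, always_pos, drop = FALSE])
    ref <- colMeans(lm)  # log geometric means
    sf <- exp(apply(lm, 1, function(r) median(r - ref)))
  } else {
    inform("size_factors: no feature positive in all samples; using total-count scaling")
    tot <- rowSums(m)
    sf <- tot / exp(mean(log(tot)))
  }
  sf / exp(mean(log(sf)))
}

#' Negative binomial Wald test for differential abundance
#'
#' Per-feature NB generalized linear model with a log link, a two-level group
#' indicator and a log size-factor offset; the dispersion is estimated per
#' feature by maximum likelihood ([MASS::glm.nb()]). The Wald statistic is
#' `z = beta / SE`; p-values are BH-adjusted and a feature is called
#' significant when `q < fdr` AND `|log2FC| >= lfc_threshold`.
#'
#' @param counts sample table of integer counts.
#' @param groups two-level grouping; the first factor level is the reference
#'   (log2FC > 0 means increased in the non-reference group).
#' @param lfc_threshold absolute log2 fold-change cutoff (default 1).
#' @param fdr BH q-value cutoff (default 0.01).
#' @return tibble: `feature`, `base_mean`, `log2fc`, `se`, `wald_z`,
#'   `p_value`, `q_value`, `direction`, `significant`, `flag`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_otus = 30, n_guilds = 3, seed = 3))
#' grp <- factor(ifelse(coh$clinical$cohort == "control", "control", "patient"),
#'               levels = c("control", "patient"))
#' res <- nb_wald_test(coh$counts, grp)
#' head(res)
#' @export
nb_wald_test <- function(counts, groups, lfc_threshold = 1, fdr = 0.01) {
  m <- as_sample_matrix(counts)
  g <- check_two_groups(groups)
  if (length(g) != nrow(m)) abort("groups must align with samples")
  sf <- size_factors(counts)
  off <- log(sf)

  fit_one <- function(y) {
    if (all(y == 0)) {
      return(c(NA, NA, NA, NA, flag = 1))
    }
    est <- tryCatch({
      fit <- suppressWarnings(MASS::glm.nb(y ~ g + offset(off)))
      s <- summary(fit)$coefficients
      c(s[2, 1], s[2, 2], s[2, 3], s[2, 4], 0)
    }, error = function(e) {
      # quasi-Poisson fallback for degenerate features
      fit <- suppressWarnings(glm(y ~ g + offset(off), family = stats::quasipoisson()))
      s <- summary(fit)$coefficients
      c(s[2, 1], s[2, 2], s[2, 3],
        2 * pnorm(abs(s[2, 3]), lower.tail = FALSE), 2)
    })
    est
  }

  est <- t(apply(m, 2, fit_one))
  out <- tibble(
    feature = colnames(m),
    base_mean = colMeans(m / sf),
    log2fc = est[, 1] / log(2),
    se = est[, 2] / log(2),
    wald_z = est[, 3],
    p_value = est[, 4],
    flag = dplyr::case_match(est[, 5], 0 ~ NA_character_,
                             1 ~ "all zero; skipped",
                             2 ~ "NB fit failed; quasi-Poisson fallback")
  )
  tested <- !is.na(out$p_value)
  out$q_value <- NA_real_
  out$q_value[tested] <- bh_adjust(out$p_value[tested])
  out$direction <- dplyr::case_when(
    is.na(out$log2fc) ~ NA_character_,
    out$log2fc > 0 ~ "increased",
    out$log2fc < 0 ~ "decreased",
    TRUE ~ "none"
  )
  out$significant <- !is.na(out$q_value) & out$q_value < fdr &
    abs(out$log2fc) >= lfc_threshold
  n_skip <- sum(!tested)
  if (n_skip) inform(sprintf("nb_wald_test: %d all-zero features skipped", n_skip))
  out[, c("feature", "base_mean", "log2fc", "se", "wald_z", "p_value",
          "q_value", "direction", "significant", "flag")]
}

#' Microbial dysbiosis index
#'
#' Per-sample `log10` of the summed relative abundance of disease-increased
#' taxa over the summed relative abundance of disease-decreased taxa, with a
#' small guard `eps` keeping the ratio finite. Depends only on relative
#' abundances, so it is invariant to sequencing depth.
#'
#' @param counts sample table of OTU counts.
#' @param increased,decreased disjoint, non-empty character vectors of taxon
#'   ids (typically the significant increased/decreased sets from
#'   [nb_wald_test()]).
#' @param eps pseudo-abundance guard added to both sums (default `1e-6`).
#' @return tibble: `sample_id`, `md_index`, plus the two summed abundances.
#' @export
md_index <- function(counts, increased, decreased, eps = 1e-6) {
  if (!length(increased) || !length(decreased)) {
    abort("both taxa sets must be non-empty")
  }
  if (length(intersect(increased, decreased))) {
    abort("increased and decreased sets overlap")
  }
  rel <- as_sample_matrix(relative_abundance(counts))
  missing <- setdiff(c(increased, decreased), colnames(rel))
  if (length(missing)) {
    abort(paste0("taxa absent from counts: ", paste(head(missing, 5), collapse = ", ")))
  }
  up <- unname(rowSums(rel[, increased, drop = FALSE]))
  dn <- unname(rowSums(rel[, decreased, drop = FALSE]))
  tibble(sample_id = rownames(rel),
         sum_increased = up, sum_decreased = dn,
         md_index = log10((up + eps) / (dn + eps)))
}

#' Spearman correlation with exact small-sample p-values
#'
#' Midrank-based Spearman rho; the p-value is exact (permutation
#' distribution) for n <= 9 without ties, and uses the t approximation with
#' tie-corrected midranks otherwise.
#'
#' @param x,y aligned numeric vectors (n >= 3, finite).
#' @return one-row tibble with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("spearman_test needs at least 3 finite pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(rho = NA_real_, p_value = NA_real_, n = n,
                  method = "undefined: constant input"))
  }
  rho <- cor(rank(x), rank(y))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 9 && !ties) {
    ct <- cor.test(x, y, method = "spearman", exact = TRUE)
    return(tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
                  method = "exact"))
  }
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- if (abs(rho) >= 1) 0 else 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  tibble(rho = rho, p_value = p, n = n, method = "t approximation")
}

#' MD-index associations with disease severity and richness
#'
#' Spearman correlations of the per-sample MD-index against the mRS severity
#' score and against observed species richness, over the supplied (patient)
#' samples.
#'
#' @param md result of [md_index()].
#' @param mrs named (by sample id) or aligned numeric severity scores.
#' @param richness named or aligned numeric richness values.
#' @return two-row tibble (`against` = "mrs", "richness") with `rho`,
#'   `p_value`, `n`, `method`.
#' @export
md_severity_association <- function(md, mrs, richness) {
  align <- function(v) {
    if (!is.null(names(v))) {
      ix <- match(md$sample_id, names(v))
      v <- v[ix]
    } else if (length(v) != nrow(md)) {
      abort("covariates must be named by sample id or aligned with `md`")
    }
    v
  }
  dplyr::bind_rows(
    mutate(spearman_test(md$md_index[!is.na(align(mrs))],
                         align(mrs)[!is.na(align(mrs))]), against = "mrs"),
    mutate(spearman_test(md$md_index[!is.na(align(richness))],
                         align(richness)[!is.na(align(richness))]),
           against = "richness")
  )
}
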