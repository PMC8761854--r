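#' Run the full multi-omic analysis on a cohort
#'
#' Chains every stage over a [simulate_cohort()]-shaped object (or any list
#' with the same tables): ecology (alpha/beta diversity, ordination,
#' community tests), guilds (OTU filter, SparCC, CAG clustering and group
#' tests), dysbiosis (NB Wald differential taxa, MD-index and its severity
#' associations), metabolome for both compartments (preprocessing, PLS-DA
#' with VIP selection, module detection, pathway enrichment), integration
#' (cytokine tests, genus-cytokine grid, cross-omic FDR network) and
#' prognosis (random-forest outcome model, adjusted odds ratio, combined
#' marker panel, relapse survival). A failing stage aborts with its name;
#' results computed so far are attached to the error condition.
#'
#' @param cohort a `guild_cohort` or compatible list (`counts`, `taxonomy`,
#'   `tree`, `fecal`, `serum`, `annotation`, `clinical`, `cytokines`).
#' @param n_cags CAG count for clustering (capped at the retained OTUs).
#' @param min_total,min_prevalence OTU filter thresholds.
#' @param fdr_taxa q-value threshold for differential taxa (default 0.01).
#' @param fdr_network q-value threshold for network edges (default 0.05).
#' @param lfc_threshold log2 fold-change threshold for taxa (default 1).
#' @param vip_threshold VIP threshold for metabolite selection (default 1).
#' @param n_perm permutations for PLS-DA validation and community tests.
#' @param n_trees random-forest size.
#' @param sparcc_bootstraps null resamples for SparCC pseudo p-values
#'   (default 0: the partition only needs the correlation matrix).
#' @param seed master seed; each stochastic stage derives its own from it.
#' @return object of class `guild_analysis`: one element per stage plus
#'   `provenance` (package version, parameter hash, seed, thresholds).
#' @examples
#' \donttest{
#' coh <- simulate_cohort(cohort_config(n_otus = 60, n_guilds = 6,
#'                                      n_fecal_mets = 60, n_serum_mets = 60,
#'                                      n_modules = 4, seed = 11))
#' res <- run_analysis(coh, n_cags = 6, n_perm = 49, n_trees = 200)
#' res$prognosis$rf$auc
#' }
#' @export
run_analysis <- function(cohort,
                         n_cags = 19,
                         min_total = 1000,
                         min_prevalence = 0.2,
                         fdr_taxa = 0.01,
                         fdr_network = 0.05,
                         lfc_threshold = 1,
                         vip_threshold = 1,
                         n_perm = 999,
                         n_trees = 1000,
                         sparcc_bootstraps = 0,
                         seed = 1) {
  params <- list(n_cags = n_cags, min_total = min_total,
                 min_prevalence = min_prevalence, fdr_taxa = fdr_taxa,
                 fdr_network = fdr_network, lfc_threshold = lfc_threshold,
                 vip_threshold = vip_threshold, n_perm = n_perm,
                 n_trees = n_trees, sparcc_bootstraps = sparcc_bootstraps,
                 seed = seed)
  out <- list(provenance = list(
    package_version = as.character(utils::packageVersion("guildomics")),
    parameter_hash = rlang::hash(params),
    parameters = params,
    started = format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  ))
  stage <- function(name, expr) {
    inform(sprintf("[%s] running", name))
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            parent = e, partial = out)
    })
  }

  cl <- cohort$clinical
  grp3 <- setNames(cl$group, cl$sample_id)
  grp2 <- factor(ifelse(grp3 == "control", "control", "patient"),
                 levels = c("control", "patient"))
  names(grp2) <- cl$sample_id
  patients <- cl$sample_id[cl$cohort == "patient"]

  out$ecology <- stage("ecology", {
    alpha <- alpha_diversity(cohort$counts)
    d <- unifrac_distance(cohort$counts, cohort$tree)
    ids <- attr(d, "Labels")
    list(alpha = alpha,
         unifrac = d,
         pcoa = pcoa_ordination(d, k = 2),
         anosim = anosim_test(d, grp3[ids], n_perm = n_perm, seed = seed),
         permanova = permanova_test(d, grp3[ids], n_perm = n_perm, seed = seed))
  })

  out$guilds <- stage("guilds", {
    retained <- filter_otus(cohort$counts, min_total, min_prevalence)
    fit <- sparcc(retained, n_bootstraps = sparcc_bootstraps, seed = seed + 1)
    part <- cluster_cags(fit, n_cags = min(n_cags, ncol(fit$rho)))
    ab <- cag_abundance(retained, part)
    sev_ctrl <- rownames(as_sample_matrix(ab$abundance))
    sev_ctrl <- sev_ctrl[grp3[sev_ctrl] %in% c("control", "severe")]
    tests <- test_cag_differences(
      ab$abundance[match(sev_ctrl, ab$abundance$sample_id), ],
      factor(grp3[sev_ctrl], levels = c("control", "severe")))
    list(retained = retained, sparcc = fit, partition = part,
         abundance = ab, tests = tests)
  })

  out$dysbiosis <- stage("dysbiosis", {
    diff <- nb_wald_test(out$guilds$retained, grp2,
                         lfc_threshold = lfc_threshold, fdr = fdr_taxa)
    inc <- diff$feature[diff$significant & diff$direction == "increased"]
    dec <- diff$feature[diff$significant & diff$direction == "decreased"]
    md <- NULL; assoc <- NULL
    if (length(inc) && length(dec)) {
      md <- md_index(out$guilds$retained, inc, dec)
      pat_md <- md[md$sample_id %in% patients, ]
      mrs <- setNames(cl$mrs_baseline, cl$sample_id)
      rich <- setNames(out$ecology$alpha$observed, out$ecology$alpha$sample_id)
      assoc <- md_severity_association(pat_md, mrs[pat_md$sample_id],
                                       rich[pat_md$sample_id])
    } else {
      inform("dysbiosis: no taxa in one direction; MD-index skipped")
    }
    list(differential = diff, increased = inc, decreased = dec,
         md = md, association = assoc)
  })

  run_metabolome <- function(raw, label) {
    ids <- raw$sample_id
    y <- droplevels(grp2[ids])
    proc <- preprocess_metabolites(raw)
    model <- plsda_fit(proc, y, n_perm = n_perm, seed = seed + 2)
    sel <- select_differential_metabolites(model, raw, y,
                                           vip_threshold = vip_threshold)
    mods <- detect_modules(proc)
    ann <- cohort$annotation[cohort$annotation$compartment == label, ]
    enr <- pathway_enrichment(sel$metabolite_id[sel$selected], ann,
                              universe = intersect(ann$metabolite_id,
                                                   sel$metabolite_id))
    list(processed = proc, plsda = model, selected = sel, modules = mods,
         enrichment = enr)
  }
  out$fecal <- stage("metabolome (fecal)", run_metabolome(cohort$fecal, "fecal"))
  out$serum <- stage("metabolome (serum)", run_metabolome(cohort$serum, "serum"))

  out$integration <- stage("integration", {
    cyt_ids <- cohort$cytokines$sample_id
    cyt_tests <- cytokine_group_tests(cohort$cytokines, droplevels(grp2[cyt_ids]))
    genus <- aggregate_genus(relative_abundance(out$guilds$retained),
                             cohort$taxonomy)
    gshared <- intersect(genus$sample_id, cyt_ids)
    grid <- genus_cytokine_correlations(
      genus[match(gshared, genus$sample_id), ],
      cohort$cytokines, groups = grp2[gshared])
    network <- build_integration_network(
      out$guilds$abundance$abundance,
      fecal_eigen = out$fecal$modules$eigen,
      serum_eigen = out$serum$modules$eigen,
      cytokines = cohort$cytokines,
      fdr = fdr_network)
    list(cytokine_tests = cyt_tests, genus_cytokine = grid, network = network)
  })

  out$prognosis <- stage("prognosis", {
    rel <- relative_abundance(out$guilds$retained)
    rel_p <- rel[rel$sample_id %in% patients, ]
    ix <- match(rel_p$sample_id, cl$sample_id)
    outcome <- factor(ifelse(cl$outcome_poor[ix] == 1, "poor", "favorable"),
                      levels = c("favorable", "poor"))
    rf <- rf_outcome_model(rel_p, outcome, n_trees = n_trees, seed = seed + 3)
    marker_otu <- rf$importance$feature[1]
    marker <- as_sample_matrix(rel_p)[, marker_otu]
    covars <- data.frame(age = cl$age[ix], sex = cl$sex[ix],
                         consciousness = cl$consciousness[ix],
                         neos = cl$neos[ix])
    # a strongly protective marker can leave an empty cell in the median
    # dichotomy; fall back to the continuous coding, then to NA, rather
    # than aborting the whole run
    or <- tryCatch(
      logistic_adjusted_or(marker, cl$outcome_poor[ix], covars),
      error = function(e) tryCatch({
        inform("prognosis: median-split marker separates; using continuous coding")
        logistic_adjusted_or(marker, cl$outcome_poor[ix], covars,
                             dichotomize = FALSE)
      }, error = function(e2) {
        inform("prognosis: separation in the adjusted model; OR not estimable")
        tibble(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
               p_value = NA_real_, beta = NA_real_, se = NA_real_,
               n = length(ix), marker_coding = "not estimable (separation)")
      }))

    top2 <- function(sel) head(sel$metabolite_id[sel$selected][
      order(-sel$vip[sel$selected])], 2)
    serum_ids <- intersect(rel_p$sample_id, cohort$serum$sample_id)
    panel <- NULL; combined <- NULL
    if (length(serum_ids) >= 20) {
      sm <- as_sample_matrix(cohort$serum)[serum_ids, top2(out$serum$selected), drop = FALSE]
      fm <- as_sample_matrix(cohort$fecal)[serum_ids, top2(out$fecal$selected), drop = FALSE]
      jx <- match(serum_ids, cl$sample_id)
      panel <- as_sample_tibble(cbind(neos = cl$neos[jx],
                                      marker = marker[serum_ids], sm, fm))
      combined <- combined_marker_model(
        panel, outcome[match(serum_ids, rel_p$sample_id)],
        baseline = rf, n_trees = n_trees, seed = seed + 4)
    }
    shan <- setNames(out$ecology$alpha$shannon, out$ecology$alpha$sample_id)
    surv <- relapse_survival(cl[cl$cohort == "patient", ],
                             diversity = shan[patients])
    list(rf = rf, marker_otu = marker_otu, adjusted_or = or,
         panel = panel, combined = combined, survival = surv)
  })

  out$provenance$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  structure(out, class = "guild_analysis")
}

#' @export
print.guild_analysis <- function(x, ...) {
  cat("<guild_analysis>\n")
  cat(sprintf("  retained OTUs: %d; CAGs: %d\n",
              ncol(x$guilds$retained) - 1, length(x$guilds$partition$members)))
  cat(sprintf("  differential taxa: %d increased, %d decreased (q < %g)\n",
              length(x$dysbiosis$increased), length(x$dysbiosis$decreased),
              x$provenance$parameters$fdr_taxa))
  cat(sprintf("  network: %d significant edges; RF AUC %.2f; relapse HR %.2f\n",
              sum(x$integration$network$edges$significant),
              x$prognosis$rf$auc, x$prognosis$survival$cox$hr))
  invisible(x)
}
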