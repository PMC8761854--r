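#' Configuration for the synthetic study cohort
#'
#' Bundles every knob of the synthetic data generator. Defaults emulate the
#' structure of a case-control autoimmune-encephalitis gut microbiome study:
#' 58 patients (22 severe, baseline mRS 4-5; 36 moderate), 49 household
#' healthy controls, roughly 300 retained OTUs organised into 19 co-abundance
#' guilds, fecal (all participants) and serum (a 70-participant subset)
#' metabolomes with planted module structure, a 15-channel cytokine panel with
#' 9 channels elevated in disease, one protective prognostic taxon, and
#' relapse hazards that depend on realised alpha diversity (hazard ratio 2.7
#' between below- and above-median Shannon groups).
#'
#' @param n_patients,n_severe,n_controls cohort sizes; `n_severe` patients
#'   get the full planted guild effect, the remaining (moderate) patients an
#'   attenuated one.
#' @param n_otus,n_guilds number of OTUs and co-abundance guilds planted.
#' @param n_affected_guilds how many guilds differ between patients and
#'   controls (roughly 2/3 depleted, 1/3 enriched in patients).
#' @param guild_effect log2 fold change applied to affected guilds in severe
#'   patients (moderate patients receive about half of it).
#' @param n_fecal_mets,n_serum_mets,n_modules metabolome dimensions; each
#'   compartment carries `n_modules` planted co-abundance modules.
#' @param n_coupled_modules how many modules per compartment are linearly
#'   coupled to guild signals.
#' @param coupling latent correlation between a coupled module and its guild
#'   signal (sign alternates across couplings).
#' @param n_cytokines,n_elevated_cytokines panel size and number of channels
#'   elevated in patients.
#' @param cytokine_effect log-scale elevation of affected cytokine channels
#'   per unit of severity score.
#' @param n_prognostic_otus size of the ranked prognostic taxon set; the
#'   k-th marker contributes `prognostic_otu_effect / k` to the outcome
#'   log-odds, so the first is the dominant marker.
#' @param prognostic_otu_effect log-odds of poor 6-month outcome per standard
#'   deviation of the dominant prognostic OTU's log relative abundance
#'   (negative = protective taxon).
#' @param relapse_hr hazard ratio for relapse between below- and above-median
#'   Shannon diversity patients.
#' @param baseline_hazard monthly relapse hazard in the high-diversity group.
#' @param followup_months administrative censoring horizon.
#' @param poor_outcome_rate expected fraction of patients with poor 6-month
#'   outcome (mRS > 2); the outcome model intercept is calibrated to it.
#' @param n_serum_patients,n_serum_controls size of the serum/cytokine
#'   subset.
#' @param seq_depth_mean,seq_depth_sdlog log-normal sequencing depth model.
#' @param richness_loss probability scale at which rare, susceptible OTUs
#'   drop out of patient samples (drives the diversity/severity gradient).
#' @param n_pathways,n_enriched_pathways annotation map dimensions; planted
#'   differential metabolites concentrate in the enriched pathways.
#' @param seed integer seed; every stage derives its randomness from it.
#'
#' @return an object of class `cohort_config` (a validated named list).
#' @examples
#' cfg <- cohort_config(seed = 1)
#' cfg$n_patients
#' @export
cohort_config <- function(n_patients = 58,
                          n_severe = 22,
                          n_controls = 49,
                          n_otus = 300,
                          n_guilds = 19,
                          n_affected_guilds = 6,
                          guild_effect = 2,
                          n_fecal_mets = 300,
                          n_serum_mets = 380,
                          n_modules = 8,
                          n_coupled_modules = 4,
                          coupling = 0.8,
                          n_cytokines = 15,
                          n_elevated_cytokines = 9,
                          cytokine_effect = 1.0,
                          n_prognostic_otus = 5,
                          prognostic_otu_effect = -2.2,
                          relapse_hr = 2.7,
                          baseline_hazard = 0.05,
                          followup_months = 6,
                          poor_outcome_rate = 0.362,
                          n_serum_patients = 39,
                          n_serum_controls = 31,
                          seq_depth_mean = 5e4,
                          seq_depth_sdlog = 0.3,
                          richness_loss = 0.4,
                          n_pathways = 20,
                          n_enriched_pathways = 3,
                          seed = 42) {
  cfg <- as.list(environment())
  counts <- c("n_patients", "n_severe", "n_controls", "n_otus", "n_guilds",
              "n_fecal_mets", "n_serum_mets", "n_modules", "n_cytokines",
              "n_pathways")
  for (f in counts) {
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] < 1) {
      abort(paste0("`", f, "` must be a single count >= 1"))
    }
  }
  if (cfg$n_severe > cfg$n_patients) abort("`n_severe` cannot exceed `n_patients`")
  if (cfg$relapse_hr <= 0) abort("`relapse_hr` must be positive")
  if (cfg$n_affected_guilds > cfg$n_guilds) abort("`n_affected_guilds` cannot exceed `n_guilds`")
  if (cfg$n_coupled_modules > cfg$n_modules) abort("`n_coupled_modules` cannot exceed `n_modules`")
  if (cfg$coupling < 0 || cfg$coupling >= 1) abort("`coupling` must lie in [0, 1)")
  if (cfg$n_serum_patients > cfg$n_patients || cfg$n_serum_controls > cfg$n_controls) {
    abort("serum subset cannot exceed the cohort")
  }
  if (cfg$n_elevated_cytokines > cfg$n_cytokines) {
    abort("`n_elevated_cytokines` cannot exceed `n_cytokines`")
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "cohort_config")
}

#' A fully effect-free version of a cohort configuration
#'
#' Sets every planted effect (guild shifts, module couplings, cytokine
#' elevation, prognostic marker, relapse hazard ratio, richness loss) to its
#' null value while keeping the dimensions. Useful for type-I-error and
#' false-discovery calibration checks.
#'
#' @param config a [cohort_config()].
#' @return a `cohort_config` with all effects nulled.
#' @export
null_config <- function(config = cohort_config()) {
  config$guild_effect <- 0
  config$coupling <- 0
  config$cytokine_effect <- 0
  config$prognostic_otu_effect <- 0
  config$relapse_hr <- 1
  config$richness_loss <- 0
  config
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  samples: %d patients (%d severe) + %d controls\n",
              x$n_patients, x$n_severe, x$n_controls))
  cat(sprintf("  microbiome: %d OTUs in %d guilds (%d affected, log2FC %.2g)\n",
              x$n_otus, x$n_guilds, x$n_affected_guilds, x$guild_effect))
  cat(sprintf("  metabolomes: %d fecal / %d serum metabolites, %d modules (%d coupled at %.2g)\n",
              x$n_fecal_mets, x$n_serum_mets, x$n_modules,
              x$n_coupled_modules, x$coupling))
  cat(sprintf("  cytokines: %d channels (%d elevated); relapse HR %.2g; seed %d\n",
              x$n_cytokines, x$n_elevated_cytokines, x$relapse_hr, x$seed))
  invisible(x)
}
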