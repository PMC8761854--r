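#' Simulate the microbiome arm of a synthetic cohort
#'
#' Draws an OTU count table with planted co-abundance guild structure. Each
#' sample gets a latent factor per guild; OTU log-abundances are the guild
#' factor plus OTU-level noise, so members of a guild covary across samples.
#' Affected guilds receive a severity-scaled log fold change in patients
#' (full in severe, roughly half in moderate), a configurable fraction of
#' rare OTUs drops out of patient samples (producing the diversity/severity
#' gradient), compositions are closed, and counts are drawn multinomially at
#' a log-normal sequencing depth. A rooted bifurcating tree is built with
#' guild members joined first so phylogenetic beta diversity is sensitive to
#' guild shifts.
#'
#' @param config a [cohort_config()].
#' @return a list with `counts` (tibble, `sample_id` + one column per OTU),
#'   `taxonomy` (tibble: `otu_id`, `genus`), `tree` (`ape::phylo`), and
#'   `truth` (ground-truth list: guild labels, affected guilds with
#'   directions, per-sample guild signals, severity scores, prognostic OTU,
#'   true differential taxa).
#' @examples
#' sim <- simulate_microbiome(cohort_config(n_otus = 40, n_guilds = 4, seed = 1))
#' dim(sim$counts)
#' @export
simulate_microbiome <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_otus / config$n_guilds < 3) {
    abort("guild sizes below 3 are undetectable; reduce `n_guilds` or add OTUs")
  }
  set.seed(config$seed)

  n_mod <- config$n_patients - config$n_severe
  sample_id <- c(sprintf("P%03d", seq_len(config$n_patients)),
                 sprintf("C%03d", seq_len(config$n_controls)))
  group <- c(sample(rep(c("severe", "moderate"), c(config$n_severe, n_mod))),
             rep("control", config$n_controls))
  n <- length(sample_id)

  # severity score drives every planted disease effect; 0 in controls
  u <- numeric(n)
  u[group == "moderate"] <- runif(sum(group == "moderate"), 0.3, 0.6)
  u[group == "severe"] <- runif(sum(group == "severe"), 0.8, 1.2)

  otu_id <- sprintf("OTU%03d", seq_len(config$n_otus))
  guild <- sort(rep_len(seq_len(config$n_guilds), config$n_otus))

  affected <- sort(sample(seq_len(config$n_guilds), config$n_affected_guilds))
  direction <- rep(c(-1L, 1L), c(ceiling(2 / 3 * config$n_affected_guilds),
                                 config$n_affected_guilds -
                                   ceiling(2 / 3 * config$n_affected_guilds)))
  names(direction) <- affected

  # guild latent factors and their realised (effect-including) signals
  f <- matrix(rnorm(config$n_guilds * n), config$n_guilds, n,
              dimnames = list(NULL, sample_id))
  h <- f
  for (k in affected) {
    h[k, ] <- f[k, ] + direction[[as.character(k)]] * config$guild_effect * log(2) * u
  }

  base <- rnorm(config$n_otus, 0, 1.2)
  eps <- matrix(rnorm(config$n_otus * n, 0, 0.5), config$n_otus, n)
  logab <- base + h[guild, , drop = FALSE] + eps

  # prognostic markers: a ranked set of mid-abundance OTUs from unaffected
  # guilds (any guild when every guild is affected); the first is the
  # dominant marker, later ones carry decaying outcome effects
  unaffected_otus <- which(!guild %in% affected)
  if (!length(unaffected_otus)) unaffected_otus <- seq_along(otu_id)
  mid <- unaffected_otus[order(abs(base[unaffected_otus] - stats::median(base)))]
  prognostic <- otu_id[mid[seq_len(min(config$n_prognostic_otus, length(mid)))]]

  # rare-OTU dropout in patients (susceptible = low-abundance, unaffected)
  susceptible <- intersect(unaffected_otus,
                           which(base <= quantile(base, 0.4)))
  susceptible <- setdiff(susceptible, match(prognostic, otu_id))
  abund <- exp(logab)
  if (config$richness_loss > 0 && length(susceptible)) {
    for (s in which(u > 0)) {
      p_loss <- min(config$richness_loss * u[s], 0.9)
      drop <- runif(length(susceptible)) < p_loss
      abund[susceptible[drop], s] <- 0
    }
  }

  depth <- round(rlnorm(n, log(config$seq_depth_mean), config$seq_depth_sdlog))
  counts <- matrix(0L, n, config$n_otus, dimnames = list(sample_id, otu_id))
  for (s in seq_len(n)) {
    counts[s, ] <- as.integer(rmultinom(1, depth[s], abund[, s] / sum(abund[, s])))
  }

  taxonomy <- assign_taxonomy(otu_id, guild, prognostic)
  tree <- guild_tree(otu_id, guild)

  truth <- list(
    sample_id = sample_id,
    group = setNames(group, sample_id),
    severity_score = setNames(u, sample_id),
    depth = setNames(depth, sample_id),
    otu_guild_labels = setNames(guild, otu_id),
    affected_guilds = tibble(guild = affected,
                             direction = unname(direction[as.character(affected)])),
    guild_signal = h,
    prognostic_otus = prognostic,
    true_differential_taxa = tibble(
      otu_id = otu_id[guild %in% affected],
      direction = unname(direction[as.character(guild[guild %in% affected])])
    ),
    susceptible_otus = otu_id[susceptible]
  )

  list(counts = as_sample_tibble(counts), taxonomy = taxonomy,
       tree = tree, truth = truth)
}

# genus pool reflecting taxa commonly reported in gut dysbiosis studies;
# the dominant prognostic OTU is labelled Granulicatella, two genera per guild
assign_taxonomy <- function(otu_id, guild, prognostic) {
  pool <- c("Bacteroides", "Faecalibacterium", "Ruminococcus", "Anaerostipes",
            "Butyricicoccus", "Eubacterium_hallii_group", "Megamonas",
            "Enterococcus", "Fusicatenibacter", "Sellimonas", "Prevotella",
            "Bifidobacterium", "Roseburia", "Clostridium_innocuum_group",
            "Lachnospiraceae_NK4A136_group", "Lachnospiraceae_NC2004_group",
            "Blautia", "Dorea", "Streptococcus", "Oscillibacter", "Alistipes",
            "Parabacteroides", "Akkermansia", "Dialister", "Coprococcus",
            "Phascolarctobacterium", "Veillonella", "Collinsella",
            "Subdoligranulum", "Agathobacter")
  n_guilds <- max(guild)
  genus <- character(length(otu_id))
  for (k in seq_len(n_guilds)) {
    members <- which(guild == k)
    g2 <- pool[(((k - 1) * 2) %% length(pool)) + 1:2]
    genus[members] <- sample(g2, length(members), replace = TRUE)
  }
  genus[otu_id == prognostic[1]] <- "Granulicatella"
  tibble(otu_id = otu_id, genus = genus)
}

# random coalescent-style joins, guild members first, Exp(1) branch lengths
guild_tree <- function(otu_id, guild) {
  join_random <- function(parts) {
    while (length(parts) > 1) {
      pick <- sample(length(parts), 2)
      merged <- sprintf("(%s:%.6f,%s:%.6f)", parts[pick[1]], rexp(1),
                        parts[pick[2]], rexp(1))
      parts <- c(parts[-pick], merged)
    }
    parts
  }
  subtrees <- vapply(seq_len(max(guild)), function(k) {
    join_random(otu_id[guild == k])
  }, character(1))
  ape::read.tree(text = paste0(join_random(subtrees), ";"))
}

#' Simulate fecal and serum metabolomes coupled to the microbiome
#'
#' Each compartment carries planted co-abundance modules: metabolite
#' log-intensities are a loading times their module's latent factor plus
#' noise, on a log-normal intensity scale. A configurable number of module
#' latents is linearly coupled (with alternating sign) to planted guild
#' signals, so microbial shifts propagate into the metabolome. A pathway
#' annotation map is drawn with differential metabolites concentrated in a
#' few enriched pathways.
#'
#' @param config a [cohort_config()].
#' @param truth ground truth from [simulate_microbiome()].
#' @return list with `fecal` and `serum` intensity tables (tibbles), the
#'   `annotation` map (tibble: `metabolite_id`, `pathway`, `compartment`),
#'   and the updated `truth` (module labels, latents, couplings, direct
#'   differential metabolites, enriched pathways, serum subset).
#' @export
simulate_metabolomes <- function(config, truth) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed + 1L)

  patients <- truth$sample_id[truth$group != "control"]
  controls <- truth$sample_id[truth$group == "control"]
  serum_samples <- c(sort(sample(patients, config$n_serum_patients)),
                     sort(sample(controls, config$n_serum_controls)))

  affected <- truth$affected_guilds$guild
  guild_pool <- c(affected, setdiff(seq_len(config$n_guilds), affected))

  one_compartment <- function(prefix, n_mets, samples) {
    n <- length(samples)
    u <- truth$severity_score[samples]
    met_id <- sprintf("%s_met%03d", prefix, seq_len(n_mets))
    module <- sort(rep_len(seq_len(config$n_modules), n_mets))

    coupled <- seq_len(config$n_coupled_modules)
    map <- tibble(
      module = coupled,
      guild = guild_pool[((coupled - 1) %% length(guild_pool)) + 1],
      sign = ifelse(coupled %% 2 == 1, 1L, -1L),
      coupling = config$coupling
    )

    latents <- matrix(rnorm(config$n_modules * n), config$n_modules, n,
                      dimnames = list(NULL, samples))
    if (config$coupling > 0) {
      for (i in seq_len(nrow(map))) {
        g <- as.numeric(scale(truth$guild_signal[map$guild[i], samples]))
        latents[map$module[i], ] <- map$sign[i] * config$coupling * g +
          sqrt(1 - config$coupling^2) * latents[map$module[i], ]
      }
    }

    pathway <- sprintf("%s_pathway%02d", prefix,
                       sample(rep_len(seq_len(config$n_pathways), n_mets)))
    enriched <- sprintf("%s_pathway%02d", prefix, seq_len(config$n_enriched_pathways))
    w <- ifelse(pathway %in% enriched, 8, 1)
    n_direct <- min(40, floor(n_mets / 5))
    direct <- sample(n_mets, n_direct, prob = w)
    direct_dir <- sample(c(-1, 1), n_direct, replace = TRUE)

    loading <- runif(n_mets, 0.7, 1) * sample(c(-1, 1), n_mets, TRUE, c(0.3, 0.7))
    z <- loading * latents[module, , drop = FALSE] +
      matrix(rnorm(n_mets * n, 0, 0.6), n_mets, n)
    if (config$guild_effect > 0) {
      z[direct, ] <- z[direct, ] + direct_dir %o% u
    }
    mu <- runif(n_mets, 2.5, 5.5)
    intensity <- t(10^(mu + 0.3 * z))
    dimnames(intensity) <- list(samples, met_id)

    list(table = as_sample_tibble(intensity),
         annotation = tibble(metabolite_id = met_id, pathway = pathway,
                             compartment = prefix),
         module_labels = setNames(module, met_id),
         latents = latents, coupling_map = map,
         direct_differential = tibble(metabolite_id = met_id[direct],
                                      direction = direct_dir),
         enriched_pathways = enriched)
  }

  fec <- one_compartment("fecal", config$n_fecal_mets, truth$sample_id)
  ser <- one_compartment("serum", config$n_serum_mets, serum_samples)

  truth$serum_samples <- serum_samples
  truth$module_labels <- list(fecal = fec$module_labels, serum = ser$module_labels)
  truth$module_latents <- list(fecal = fec$latents, serum = ser$latents)
  truth$module_coupling <- dplyr::bind_rows(
    mutate(fec$coupling_map, compartment = "fecal"),
    mutate(ser$coupling_map, compartment = "serum")
  )
  truth$direct_differential_mets <- dplyr::bind_rows(
    mutate(fec$direct_differential, compartment = "fecal"),
    mutate(ser$direct_differential, compartment = "serum")
  )
  truth$enriched_pathways <- c(fec$enriched_pathways, ser$enriched_pathways)

  list(fecal = fec$table, serum = ser$table,
       annotation = dplyr::bind_rows(fec$annotation, ser$annotation),
       truth = truth)
}

#' Simulate clinical outcomes, relapse, and the cytokine panel
#'
#' The 6-month poor outcome (mRS > 2) is drawn from a logistic model on the
#' standardised log relative abundance of the planted prognostic OTU, with
#' the intercept calibrated so the expected poor-outcome fraction matches
#' `config$poor_outcome_rate`. Relapse times are exponential with the
#' configured hazard ratio between below- and above-median realised Shannon
#' diversity patients, censored at follow-up. NEOS scores are drawn
#' correlated with the outcome. Cytokine channels are log-normal; the
#' configured number of channels is elevated with severity and coupled to
#' affected guild signals.
#'
#' @param config a [cohort_config()].
#' @param truth ground truth from the earlier simulation stages.
#' @param counts realised OTU count table (tibble) from
#'   [simulate_microbiome()].
#' @return list with `clinical` (tibble, one row per participant),
#'   `cytokines` (tibble for the serum subset), and updated `truth`
#'   (relapse hazard classes, elevated cytokine channels).
#' @export
simulate_clinical <- function(config, truth, counts) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed + 2L)

  m <- as_sample_matrix(counts)
  patients <- truth$sample_id[truth$group != "control"]
  rel <- m / rowSums(m)

  # ranked prognostic markers: the k-th OTU contributes effect/k log-odds
  # per SD of its log relative abundance
  z <- vapply(truth$prognostic_otus, function(o) {
    lg <- log(rel[patients, o] + 1e-6)
    if (sd(lg) == 0) abort("prognostic marker abundance is constant")
    as.numeric(scale(lg))
  }, numeric(length(patients)))
  eta <- as.numeric(z %*% (config$prognostic_otu_effect /
                             seq_along(truth$prognostic_otus)))
  alpha <- uniroot(function(a) mean(plogis(a + eta)) - config$poor_outcome_rate,
                   c(-20, 20))$root
  poor <- rbinom(length(patients), 1, plogis(alpha + eta))

  shannon_p <- apply(m[patients, , drop = FALSE], 1, shannon)
  if (sd(shannon_p) == 0) {
    abort("Shannon diversity is constant across patients; median split undefined")
  }
  low_div <- shannon_p < median(shannon_p)
  rate <- config$baseline_hazard * ifelse(low_div, config$relapse_hr, 1)
  t_ev <- rexp(length(patients), rate)
  relapse_event <- as.integer(t_ev <= config$followup_months)
  relapse_time <- pmin(t_ev, config$followup_months)

  neos <- pmin(5, pmax(0, round(1 + 1.0 * poor + rnorm(length(patients), 0, 1.0))))
  grp <- truth$group[patients]
  consciousness <- rbinom(length(patients), 1,
                          ifelse(grp == "severe", 0.7, 0.25))
  mrs0 <- ifelse(grp == "severe", sample(4:5, length(patients), TRUE),
                 sample(2:3, length(patients), TRUE))
  mrs6 <- ifelse(poor == 1, sample(3:5, length(patients), TRUE),
                 sample(0:2, length(patients), TRUE))

  all_ids <- truth$sample_id
  is_pat <- all_ids %in% patients
  clinical <- tibble(
    sample_id = all_ids,
    cohort = ifelse(is_pat, "patient", "control"),
    group = unname(truth$group[all_ids]),
    age = round(ifelse(is_pat, rnorm(length(all_ids), 34.4, 13.5),
                       rnorm(length(all_ids), 32, 10.5))),
    sex = sample(c("F", "M"), length(all_ids), TRUE, c(0.62, 0.38)),
    bmi = round(rnorm(length(all_ids), 22.5, 3), 1)
  )
  clinical$age <- pmin(pmax(clinical$age, 16), 78)
  pat_ix <- match(patients, all_ids)
  clinical$mrs_baseline <- NA_integer_
  clinical$mrs_baseline[pat_ix] <- as.integer(mrs0)
  clinical$mrs_6m <- NA_integer_
  clinical$mrs_6m[pat_ix] <- as.integer(mrs6)
  clinical$outcome_poor <- NA_integer_
  clinical$outcome_poor[pat_ix] <- poor
  clinical$neos <- NA_integer_
  clinical$neos[pat_ix] <- as.integer(neos)
  clinical$consciousness <- NA_integer_
  clinical$consciousness[pat_ix] <- consciousness
  clinical$relapse_time <- NA_real_
  clinical$relapse_time[pat_ix] <- relapse_time
  clinical$relapse_event <- NA_integer_
  clinical$relapse_event[pat_ix] <- relapse_event

  cyt <- simulate_cytokines(config, truth)

  truth$true_relapse_groups <- setNames(ifelse(low_div, "low", "high"), patients)
  truth$elevated_cytokines <- cyt$elevated
  truth$cytokine_coupling <- cyt$coupling

  list(clinical = clinical, cytokines = cyt$table, truth = truth)
}

simulate_cytokines <- function(config, truth) {
  panel <- c("CCL4", "IFN-a", "IFN-g", "IL-1b", "IL-7", "IFN-b", "IL-1ra",
             "IL-10", "IL-4", "IL-6", "IL-8", "IL-12p40", "IL-18", "IL-17",
             "TNF-a")
  channels <- if (config$n_cytokines <= length(panel)) {
    panel[seq_len(config$n_cytokines)]
  } else {
    c(panel, sprintf("CK%02d", seq_len(config$n_cytokines - length(panel))))
  }
  elevated <- sample(channels, config$n_elevated_cytokines)
  samples <- truth$serum_samples %||% truth$sample_id
  u <- truth$severity_score[samples]
  affected <- truth$affected_guilds
  ix <- ((seq_along(elevated) - 1) %% nrow(affected)) + 1
  # elevated cytokines track enriched guilds positively and depleted guilds
  # negatively, so guild shifts and cytokine elevation reinforce
  coupling <- tibble(cytokine = elevated, guild = affected$guild[ix],
                     sign = affected$direction[ix])

  loglev <- matrix(rnorm(length(samples) * length(channels), log(20), 0.4),
                   length(samples), length(channels),
                   dimnames = list(samples, channels))
  for (i in seq_along(elevated)) {
    ck <- elevated[i]
    g <- as.numeric(scale(truth$guild_signal[coupling$guild[i], samples]))
    loglev[, ck] <- loglev[, ck] + config$cytokine_effect * u +
      0.5 * coupling$sign[i] * g
  }
  list(table = as_sample_tibble(exp(loglev)), elevated = elevated,
       coupling = coupling)
}

#' Simulate a complete synthetic multi-omic cohort
#'
#' Chains [simulate_microbiome()], [simulate_metabolomes()] and
#' [simulate_clinical()] under one seed, returning every table plus the
#' ground truth that downstream recovery tests compare against.
#'
#' @param config a [cohort_config()].
#' @return an object of class `guild_cohort`: a list with `config`, `counts`,
#'   `taxonomy`, `tree`, `fecal`, `serum`, `annotation`, `clinical`,
#'   `cytokines` and `truth`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_otus = 40, n_guilds = 4,
#'                                      n_fecal_mets = 40, n_serum_mets = 40,
#'                                      n_modules = 4, seed = 7))
#' coh
#' @export
simulate_cohort <- function(config = cohort_config()) {
  mb <- simulate_microbiome(config)
  met <- simulate_metabolomes(config, mb$truth)
  cl <- simulate_clinical(config, met$truth, mb$counts)
  structure(list(config = config, counts = mb$counts, taxonomy = mb$taxonomy,
                 tree = mb$tree, fecal = met$fecal, serum = met$serum,
                 annotation = met$annotation, clinical = cl$clinical,
                 cytokines = cl$cytokines, truth = cl$truth),
            class = "guild_cohort")
}

#' @export
print.guild_cohort <- function(x, ...) {
  cat("<guild_cohort>\n")
  cat(sprintf("  %d samples x %d OTUs; %d fecal / %d serum metabolites; %d cytokines\n",
              nrow(x$counts), ncol(x$counts) - 1, ncol(x$fecal) - 1,
              ncol(x$serum) - 1, ncol(x$cytokines) - 1))
  cat(sprintf("  groups: %s\n",
              paste(names(table(x$truth$group)), table(x$truth$group),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
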