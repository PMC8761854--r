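# shared fixtures, built once per session and cached

.fixture_env <- new.env(parent = emptyenv())

cache_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a small but fully structured cohort used by most module tests
small_config <- function(...) {
  defaults <- list(n_otus = 60, n_guilds = 6, n_affected_guilds = 3,
                   n_fecal_mets = 80, n_serum_mets = 80, n_modules = 4,
                   n_coupled_modules = 3, seed = 101)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

small_cohort <- function() {
  cache_fixture("small_cohort", function() suppressMessages(simulate_cohort(small_config())))
}

# the full default cohort and its complete analysis (study-scale; shared by
# the structure-recovery and end-to-end acceptance checks)
default_cohort <- function() {
  cache_fixture("default_cohort", function() suppressMessages(simulate_cohort(cohort_config(seed = 42))))
}

default_analysis <- function() {
  cache_fixture("default_analysis", function() {
    suppressMessages(suppressWarnings(run_analysis(default_cohort())))
  })
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

patient_groups <- function(cohort) {
  cl <- cohort$clinical
  g <- factor(ifelse(cl$cohort == "control", "control", "patient"),
              levels = c("control", "patient"))
  names(g) <- cl$sample_id
  g
}

# tiny deterministic count table: samples in rows
toy_counts <- function(m, ids = NULL) {
  ids <- ids %||% sprintf("s%d", seq_len(nrow(m)))
  colnames(m) <- colnames(m) %||% sprintf("OTU%d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(sample_id = ids),
                   tibble::as_tibble(as.data.frame(m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
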