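# guildomics

Guild-level integration of gut microbiome, metabolome and cytokine data for
case-control cohorts with clinical follow-up.

Severe autoimmune and neurological diseases often come with gut dysbiosis:
whole groups of co-varying bacteria (ecological "guilds", or co-abundance
groups, CAGs) shift together, the shifts propagate into fecal and serum
metabolites, and both correlate with circulating cytokines and with how the
patient fares months later. Analysing such a study means running a long chain
of specialised steps, each easy to get subtly wrong. guildomics packages the
whole chain as tested, seeded, tidyverse-native R functions:

- **Ecology** — Shannon (nats) and bias-corrected Chao1
  (`S_obs + F1(F1-1)/(2(F2+1))`), unweighted UniFrac over a rooted OTU tree,
  PCoA, ANOSIM (`R = (r̄_between - r̄_within)/(n(n-1)/4)`) and PERMANOVA with
  seeded permutations.
- **Guilds** — abundance/prevalence OTU filtering, SparCC compositional
  correlation (`rho_ij = (w_i + w_j - t_ij) / 2*sqrt(w_i w_j)` from log-ratio
  variances `t_ij`, iterative strong-pair exclusion, Dirichlet resampling),
  Ward clustering of `1 - rho` into CAGs, CAG abundances/Z-scores, Wilcoxon
  group tests.
- **Dysbiosis** — per-taxon negative-binomial Wald tests (ML dispersion,
  median-of-ratios size factors, BH, |log2FC| >= 1 and q < 0.01), and the
  microbial dysbiosis index
  `MD = log10(sum(increased taxa) / sum(decreased taxa))` with Spearman
  associations against severity (mRS) and richness.
- **Metabolome** — NIPALS PLS-DA with VIP
  (`VIP_j = sqrt(p * sum_a ssy_a w_aj^2 / sum_a ssy_a)`), cross-validated Q2
  and permutation validation; VIP > 1 & p < 0.05 metabolite selection;
  topological-overlap co-abundance modules with eigen-metabolites;
  hypergeometric sub-pathway enrichment with rich factors.
- **Integration** — cytokine Welch tests, genus-cytokine Spearman grids, and
  an FDR-controlled signed Spearman network across CAGs, fecal/serum
  eigen-metabolites and cytokines.
- **Prognosis** — cross-validated probability random forest with per-tree
  permutation importance (mean decrease accuracy) and Mann-Whitney AUC,
  combined marker panels, covariate-adjusted logistic odds ratios, and
  Kaplan-Meier / log-rank / Cox relapse analysis stratified by the Shannon
  median split.
- **Synthetic cohorts** — `simulate_cohort()` generates a full multi-omic
  study (microbiome with planted guilds, coupled metabolite modules,
  cytokines, outcomes and relapse) with known ground truth, so every stage
  is validated end-to-end against planted structure.

Everything takes a data frame (first column `sample_id`) and returns tibbles
or small S3 result objects with `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` ggplot2 graphics.

## A worked example

```r
library(guildomics)

cohort <- simulate_cohort(cohort_config(seed = 42))
res <- run_analysis(cohort)
res
#> <guild_analysis>
#>   retained OTUs: 286; CAGs: 19
#>   differential taxa: 30 increased, 58 decreased (q < 0.01)
#>   network: 80 significant edges; RF AUC 0.80; relapse HR 2.92

res$prognosis$rf
#> <rf_outcome> repeated stratified 5 x 5-fold CV, 1000 trees
#>   AUC = 0.802 (95% CI 0.669-0.910); sens 0.91 / spec 0.63 at Youden point
#>   top features: OTU228, OTU232, OTU237

res$dysbiosis$association
#> # A tibble: 2 x 5
#>      rho      p_value     n method          against
#>    <dbl>        <dbl> <int> <chr>           <chr>
#> 1  0.541 0.0000119       58 t approximation mrs
#> 2 -0.638 0.0000000722    58 t approximation richness

res$prognosis$survival
#> <relapse_survival> 58 patients, 23 events
#>   log-rank p = 0.01337; HR (low vs high diversity) = 2.92 (95% CI 1.20-7.11)
```

Reading those numbers: 286 of 300 simulated OTUs pass the abundance filter
and cluster into 19 co-abundance groups; 88 taxa are differentially abundant
between patients and controls, and the dysbiosis index built from them rises
with disease severity (Spearman rho 0.54) while falling with species richness
(rho -0.64). The random forest predicts the 6-month outcome from taxa alone
with a cross-validated AUC of 0.80 and ranks the planted protective marker
(OTU228, *Granulicatella*) first; patients below the median Shannon diversity
relapse at about 2.9 times the hazard of the rest.

`cohort$truth` carries the generator's ground truth (guild labels, module
latents, couplings, prognostic taxa, hazard classes), which is what the test
suite scores the pipeline against.

## Package layout

- `R/` — one file per stage (`simulate`, `ecology`, `guilds`, `dysbiosis`,
  `metabolome`, `integration`, `prognosis`, `run-all`, `io`, plus tidiers
  and plots).
- `vignettes/guild-multiomics.Rmd` — the methods vignette: models,
  assumptions, parameter choices, generator design and known limitations.
- `tests/testthat/` — unit, property and acceptance suites, including exact
  brute-force oracles for UniFrac, rank tests, enrichment, AUC and odds
  ratios, and calibration/recovery checks against planted ground truth.
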