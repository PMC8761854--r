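Package: guildomics
Title: Guild-Level Integration of Microbiome, Metabolome and Cytokine Data
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for case-control gut microbiome
    studies that integrate 16S OTU profiles with fecal and serum metabolomes,
    serum cytokines and clinical outcomes. Implements SparCC compositional
    correlation with co-abundance group (guild) clustering, alpha/beta
    diversity with unweighted UniFrac, PCoA, ANOSIM and PERMANOVA, negative
    binomial Wald differential abundance and the microbial dysbiosis index,
    PLS-DA with VIP-based metabolite selection and permutation validation,
    topological-overlap metabolite modules with eigen-metabolites,
    hypergeometric pathway enrichment, an FDR-controlled cross-omic Spearman
    network, and a prognostic layer (cross-validated random forest with
    permutation importance, covariate-adjusted logistic odds ratios, and
    Kaplan-Meier/Cox relapse analysis). A synthetic cohort generator with
    planted guild, module, cytokine and outcome structure provides ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    MASS,
    picante,
    purrr,
    ranger,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    DESeq2,
    jsonlite,
    mclust,
    mixOmics,
    phangorn,
    pROC,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
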