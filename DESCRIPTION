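Package: aerocore
Title: Decontamination and Core-Microbiome Inference for Low-Biomass Aerobiome Metagenomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-classification analysis pipeline for low-biomass air
    (aerobiome) shotgun metagenomics across cities and years: ingestion of
    Kraken2 report and Bracken species-table dialects, identification and
    removal of exogenous contaminant taxa from negative controls with a
    two-proportion Z-test prevalence gate, abundance-threshold filtering,
    per-sample read-count normalization with log transform, Shannon alpha
    diversity with Tukey HSD letter displays, PCA/UMAP beta-diversity
    ordination, forward-stepwise MANOVA on Pillai's trace for city, year,
    environmental and human covariates, and global/local core and sub-core
    microbiome inference by species prevalence at multiple abundance levels.
    Includes a synthetic taxon-count generator with planted ground truth so
    the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
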