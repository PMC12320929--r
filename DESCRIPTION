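Package: phenoproteo
Title: Molecular Phenomapping of High-Dimensional Plasma Proteomics Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives molecular phenogroups from high-dimensional aptamer-based
    plasma proteomics (samples x features abundance matrices) by median-absolute-
    deviation feature filtering, correlated-module hub selection, and consensus
    k-means clustering with PAC-based selection of the number of groups.
    Provides cluster-stability validation (in-group proportion, Rand index,
    optimal-matching concordance, hub-randomization and threshold-grid
    sensitivity analyses), permutation variable importance for unsupervised
    phenogroups, and Kaplan-Meier / Cox proportional-hazards survival
    comparisons across phenogroups. Includes a synthetic-cohort generator that
    emulates the statistical structure of a population-based heart-failure
    proteomics study so the entire pipeline is testable without access to
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
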