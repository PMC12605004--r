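Package: omninet
Title: Network-Guided Integration of Plasma Proteomics and Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for network-guided analysis of paired
    plasma proteomic (aptamer RFU) and metabolomic (scaled-imputed) profiles
    across clinical subgroups, developed around rheumatoid arthritis cohorts
    stratified by anti-citrullinated protein antibody (ACPA) status.
    Provides quality control and preprocessing for both omic blocks,
    covariate-adjusted differential abundance testing with Cohen's d effect
    size gating, subgroup-stratified Spearman correlation against clinical
    inflammation markers, one-tailed Fisher exact set enrichment (with an
    EASE-style conservative variant), elastic-net neighborhood-selection
    network inference, random-walk-with-restart feature prioritization,
    leakage-free stratified cross-validated random-forest classification
    with selector baselines, cohort characteristics tables, and a synthetic
    cohort generator with planted effects for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    Matrix,
    igraph,
    ranger,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
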