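Package: agingaxes
Title: Metabolome-Phenome Integration via LASSO Coefficient-Matrix PCA
Version: 0.1.0
Authors@R: person("Maintainer", "Developer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for integrating circulating metabolite profiles with
    multi-domain aging phenotypes in epidemiological cohorts. Metabolites pass
    presence and coefficient-of-variation quality control, half-minimum
    imputation and log-standardization; phenotypes are harmonized to a
    healthier-is-higher orientation. Per-phenotype LASSO models over the
    correlation-pruned metabolome are summarized by principal component
    analysis of the coefficient matrix, yielding aging "axes" with phenotype
    loadings and metabolite weights from which per-participant metabolic
    scores are built, transferred across cohorts, and related to time-to-event
    outcomes (proportional-hazards models, Kaplan-Meier tertile curves) and to
    pathways via hypergeometric over-representation of mapped genes. A
    synthetic two-cohort generator with planted latent axes provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    survival,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
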