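Package: irsval
Title: Immunotherapy Response Score Validation Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating the Immunotherapy Response Score (IRS), an
    integrative biomarker combining tumor mutation burden (TMB) with four
    immune and proliferation gene expression measurements to predict benefit
    from anti-PD-(L)1 therapy in advanced solid tumors. Provides the locked
    linear scoring model with two- and three-group classification, tumor-only
    TMB candidate-mutation filtering (population-database, allele-frequency
    window and clonality rules), derivation of real-world progression-free
    survival and overall survival from longitudinal therapy-line records,
    cohort assembly with auditable eligibility filters, covariate-adjusted
    Cox proportional-hazards analyses with nested-model likelihood-ratio
    tests, restricted mean survival time, Schoenfeld proportional-hazards
    checks and power calculations, case cross-over PFS-ratio analyses,
    Mantel-Haenszel stratified odds ratios, overlap-weighting propensity
    comparisons, and a calibrated synthetic cohort generator for end-to-end
    testing of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival (>= 3.4),
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR
Config/testthat/edition: 3
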