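Package: progbias
Title: Polygenic Risk Scores and Disease Progression Under Index Event Bias
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying whether a polygenic risk score built from
    disease-incidence GWAS summary statistics predicts subsequent events among
    prevalent cases, and for quantifying and correcting the index event
    (collider) bias that distorts such case-only associations. Implements
    summary-statistic ingestion, allele harmonization, LD clumping and pruning,
    P-value-thresholded score construction, stratified logistic association
    with heterogeneity testing, covariate profiles at score quantiles, and the
    index-event-bias correction: naive, Hedges-Olkin and SIMEX estimates of the
    cross-SNP bias slope, the I2GX measurement-error diagnostic, per-SNP beta
    adjustment, and fixed-effect inverse-variance-weighted estimation before
    and after correction. A liability-threshold cohort simulator with a shared
    unmeasured risk factor and survival-dependent recruitment reproduces the
    collider structure with known ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
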