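Package: SubtypeTME
Title: Tumor Microenvironment Heterogeneity Analysis Across Cancer Subtypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies tumor-microenvironment (TME) heterogeneity across
    molecular cancer subtypes from bulk expression cohorts. Provides a
    single-sample gene set enrichment (ssGSEA) engine; named per-sample TME
    feature scores (immune/stromal/purity, MHC class I score, T-cell-inflamed
    GEP, tumor mutation burden); one-vs-rest Cohen's d effect-size profiling
    with Mann-Whitney/Kruskal-Wallis testing; marker-set cell-infiltration
    scoring; the cell-based subtype set enrichment analysis (SubSEA) statistic
    with a gene-permutation null; prognostic screening of subtype-specific
    cells (univariate Cox, maximally selected cutpoints, Kaplan-Meier); and
    subtype-specific somatic mutation and copy-number association tests. A
    synthetic cohort generator with known ground truth supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
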