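Package: ProteoPDX
Title: Proteogenomic Integration and Druggable-Target Nomination for Xenograft Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A proteogenomic integration pipeline for multi-omic tumour cohorts
    profiled at the copy-number, mRNA, protein and phosphosite levels, modelled
    on breast cancer patient-derived xenograft (PDX) studies. Implements
    two-component Gaussian mixture re-centering of isobaric-label log-ratios,
    isoform-to-gene collapsing, per-gene mRNA-protein correlation with
    Kolmogorov-Smirnov pathway enrichment, variable-marker hierarchical
    subtyping with a PDX/human co-clustering filter, subtype differential
    expression with rank-based gene-set enrichment, IQR-based druggable
    expression-outlier scoring with cross-level and human-cohort validation,
    phosphoproteomic pathway-activation scoring via modified z-scores and
    rank-sum tests, tumour/xenograft variant-allele-fraction concordance, and a
    fully specified synthetic multi-omic cohort generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    SummarizedExperiment,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
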