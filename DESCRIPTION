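Package: prsbench
Title: Benchmarking Polygenic Risk Score Construction and Risk Models for
    Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for benchmarking polygenic risk score (PRS)
    strategies in case/control cohorts: GWAS summary-statistics harmonization,
    LD clumping and p-value thresholding (C+T), region-restricted scoring
    (APOE region, microglia-selective regions), external per-SNP weight
    ingestion, APOE e2/e4 diplotype calling, five logistic risk models with
    AUC evaluation and Bonferroni accounting, and individual-level score
    consistency (Pearson correlation and risk-quintile tail overlap). A
    liability-threshold simulator with block-LD genotypes, a major-effect
    APOE-like locus and paired genetically correlated discovery GWAS provides
    ground-truth data in place of access-restricted cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
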