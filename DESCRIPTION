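Package: memewas
Title: Epigenome-Wide Association Pipeline for Episodic Memory Phenotypes
Version: 0.1.0
Authors@R: person("Pipeline", "Maintainers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested, reusable pipeline for epigenome-wide association
    analysis of episodic-memory performance from Illumina-array DNA
    methylation beta-values. Covers construction of cross-sectional
    (age-residualized first principal component of memory tests) and
    longitudinal (mean annual percentage change) phenotypes,
    reference-based cell-type deconvolution by constrained least squares,
    methylation principal-component covariates, vectorized per-CpG linear
    models with genomic-inflation diagnostics, inverse-variance
    fixed-effect meta-analysis, poly-epigenetic scores, multi-tissue
    epigenetic-clock age acceleration, cis-mQTL scans, and DNAm-mRNA
    correlation in paired brain samples. Ships a synthetic multi-cohort
    data generator emulating the sample structure of a two-site aging
    cohort design so that every stage is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    matrixStats
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
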