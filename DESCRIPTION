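Package: micnet
Title: Cross-Platform Multi-Omics Correlation Networks via the Maximal
    Information Coefficient
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates DNA methylation beta values, NanoString-style miRNA
    counts, qPCR delta-Ct panels, SNP genotypes and clinical phenotypes into a
    single fused matrix and screens every cross-platform feature pair with both
    the Pearson correlation and a from-scratch Maximal Information Coefficient
    (MIC) estimator. Thresholded pairs are assembled into correlation networks
    whose hubs (nodes with four or more neighbors) are extracted and tested for
    upstream-regulator over-representation with a random-gene-list control.
    Includes per-platform QC and normalization (detection p-value and X-linked
    CpG filtering, positive-control and upper-quantile background normalization
    of counts, housekeeping delta-Ct normalization), a negative-binomial exact
    test for differential count expression, and a seeded synthetic multi-platform
    cohort generator with planted hub-and-spoke correlation structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    ape,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'micnet-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'association.R'
    'cohort-spec.R'
    'generate-cohort.R'
    'cohort-io.R'
    'differential.R'
    'enrichment.R'
    'fusion.R'
    'methods-accessors.R'
    'network.R'
    'platform-prep.R'
    'pipeline.R'
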