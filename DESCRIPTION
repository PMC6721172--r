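Package: feednet
Title: SNP Co-Association Networks and Genomic Prediction for Feed Efficiency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative systems-genetics pipeline for feed efficiency in
    half-sib livestock populations. Derives residual feed intake and feed
    conversion ratio from production records, runs mixed-model single-marker
    association scans for nine correlated traits, assembles the multi-trait
    association weight matrix (AWM) of signed z-scores, infers the SNP
    co-association network with the partial-correlation-and-information-theory
    (PCIT) algorithm, searches exhaustively for transcription-factor trios and
    quartets that span the network with minimum redundancy, integrates muscle
    transcriptome data (trend-moderated differential expression, sparse PLS
    discriminant analysis, regularized canonical correlation analysis and
    expression GWAS), and evaluates SNP panels by Gibbs-sampled variance
    components and cross-validated GBLUP prediction. A synthetic-population
    simulator with pleiotropic QTL, linkage disequilibrium, batch and
    laboratory effects makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    mixOmics,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
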