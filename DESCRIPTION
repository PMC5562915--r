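Package: sectune
Title: Tissue-Specific Expression Tuning of the Human Protein Secretory Pathway
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Meta-analysis toolkit for cross-tissue expression of the human
    protein secretory pathway. Classifies genes into the six HPA-style
    tissue-specificity categories from FPKM profiles, quantifies cross-tissue
    correlation structure of a gene set with hierarchical clustering and a
    gene-set permutation test, detects gene-family-level "extreme genes" via
    the Grubbs outlier statistic on family-share profiles with two-dataset
    consensus validation, links tissue disulfide-processing demand (an
    expression-weighted disulfide-site enrichment estimator) to
    processing-enzyme family expression by linear regression, and ships a
    fully seeded synthetic-data generator with planted ground truth so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, tools, S4Vectors, igraph, ape, jsonlite,
    yaml, withr
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, Clustering, Network
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'categories.R'
    'correlation.R'
    'extreme.R'
    'fixtures.R'
    'grubbs.R'
    'io-expression.R'
    'io-gff.R'
    'io-network.R'
    'pipeline.R'
    'ptm-load.R'
    'sectune-package.R'
    'simulate.R'
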