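Package: lncomat
Title: Integrative lncRNA-mRNA Co-Expression Analysis for Paired
    Tumor-Normal Expression Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a correlation-matrix based integrative analysis of
    long noncoding RNA (lncRNA) and mRNA expression in paired tumor-normal
    designs with a tumor-size covariate, as used in uterine leiomyoma
    profiling. Provides quantile normalization and paired differential
    expression with tumor-size signature sets, genomic-context
    classification of lncRNAs into six subtypes with cis partner
    assignment, a thresholded mRNA x lncRNA Pearson correlation matrix
    with a sum-of-absolute-correlation relevance score, hypergeometric
    gene-set enrichment with Benjamini-Hochberg correction, cross-dataset
    concordance measures, and a synthetic-data generator with a ground
    truth manifest for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    limma,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: GeneExpression, DifferentialExpression, GeneRegulation,
    Transcriptomics, Microarray, Software
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'annotation-io.R'
    'classify.R'
    'coexpr.R'
    'constructors.R'
    'diffexpr.R'
    'dscompare.R'
    'enrich.R'
    'io.R'
    'lncomat-package.R'
    'normalize.R'
    'simulate.R'
    'pipeline.R'
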