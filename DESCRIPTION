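Package: enhancerDynamics
Title: Differential Activity and Regulatory Annotation of Putative Enhancer
    Critical Regions in the Developing Brain
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Derives putative critical regions (pCRs) from multi-source
    enhancer catalogs by maximal source-overlap depth, calls differentially
    active enhancers (DAEs) across developmental stages and brain regions
    with TMM normalization and negative-binomial quasi-likelihood F-tests,
    links enhancers to genes through chromatin interactions restricted to
    topologically associating domains, profiles base-level scores across
    length-rescaled enhancer bins, computes contingency and transposable
    element enrichment statistics, and clusters DAEs by temporal epigenome
    profiles with k-medoids. A synthetic-data generator emulates every
    input with planted ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    cluster,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    edgeR,
    knitr,
    rmarkdown
biocViews: Epigenetics, FunctionalGenomics, GeneRegulation,
    DifferentialPeakCalling, Normalization, Clustering
Config/testthat/edition: 3
RoxygenNote: 7.3.3
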