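Package: miRtempo
Title: Temporal Integration of miRNA and mRNA Differential Expression
    with Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking time-course microRNA expression changes to
    downstream mRNA target changes in two-group (treated versus control)
    microarray designs. Provides detection-above-background filtering,
    robust outlier-sample removal, quantile normalization, empirical-Bayes
    moderated t-statistics with Benjamini-Hochberg false discovery rates,
    confidence filtering of miRNA-target interactions, lag-aware temporal
    pairing of differentially expressed miRNAs with their targets,
    hierarchical clustering of temporal profiles with internal validation
    (connectivity, Dunn index, silhouette), and construction of fixed-size,
    Fisher-exact-scored molecule networks on an interaction knowledgebase
    with hub and critical-gene identification.  A synthetic-data generator
    emulating a three-region, three-time-point brain study makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
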