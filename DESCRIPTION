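Package: adstagenet
Title: Stage-Wise Gene-Phenotype Correlation Screening and Process-Level
    Network Analysis for Alzheimer's Disease Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying Alzheimer's disease (AD) related genes by
    stage-wise Pearson correlation of hippocampal gene expression with
    cognitive (MMSE) and pathological (square-root NFT) scores, including
    detection-call filtering, log2 median normalization, the D'Agostino &
    Pearson omnibus normality test, and Benjamini-Hochberg adjustment
    restricted to high-R2 correlations.  Downstream, the package prunes a
    protein-protein interaction network to its giant component, classifies
    hubs and high-betweenness bottlenecks, scores biological-process
    over-representation with the EASE statistic, and integrates processes
    through stage-share coordinates, a three-space expression distance, and
    inter-process interaction counts assembled into a dual-edge process link
    graph.  A synthetic-data module generates cohorts, expression matrices
    with planted stage-specific effects, scale-free interaction networks,
    and overlapping gene sets so that every stage of the pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
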