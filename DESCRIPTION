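Package: ppnet
Title: Pathway Projection Networks from Thresholded Co-Expression Graphs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Transforms gene-expression matrices into thresholded Pearson
    correlation ("derived interaction") networks, detects topological
    communities by divisive edge-betweenness removal with modularity-based
    cut selection, and projects communities onto pathway space through a
    maximum-spanning-pathway-reduction heuristic, yielding Pathway
    Projection Networks (PPNs) and cross-pathway gene-correlation reports.
    Includes a planted-partition synthetic-data generator for benchmarking
    community recovery, per-condition network-topology summaries, and an
    end-to-end pipeline driven by a YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    SummarizedExperiment,
    S4Vectors,
    mclust,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, GeneExpression, Clustering, Pathways
RoxygenNote: 7.3.3
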