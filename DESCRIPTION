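Package: ghac
Title: Hierarchical Overlapping Community Detection in Weighted Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects hierarchical, overlapping communities in undirected
    weighted networks by agglomerative clustering of maximal cliques (GHAC).
    Cluster dissimilarities combine the weighted closed-trail distance,
    computed as a minimum-cost pair of edge-disjoint paths (Suurballe's
    algorithm), with the weight of the densest clique in the cluster overlap.
    Includes overlap-aware internal quality criteria (Shen and Lazar
    modularities, conductance and related cut scores, internal transitivity,
    Dunn index, adjusted Silhouette) for dendrogram cut selection, external
    cover-agreement metrics (overlapping NMI, F1/NF1, Omega index, overlapping
    node F1), a seeded planted-partition benchmark generator with weighted
    edges, and experiment harnesses for metric-correlation and cut-selection
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
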