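Package: warpnet
Title: Pairwise Global Alignment of Dynamic Biological Networks by Time Warping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Aligns two dynamic protein-protein interaction networks, given as
    time-ordered sequences of undirected graph snapshots, by scoring every
    cross-network node pair with a dynamic-time-warping distance over
    per-snapshot topological feature vectors (eigenvector-centrality
    reputation, degree, neighbor-reputation sum, and two-hop statistics),
    optionally blended with normalized sequence-homology scores from BLAST
    tabular output, and searching for a one-to-one node mapping that maximizes
    the summed pair scores by simulated annealing. Includes a
    duplication-divergence generator of synthetic dynamic networks with known
    ground-truth orthologs, confidence-ranked snapshot construction from
    weighted static networks, temporal and structural edge-swap randomization
    schemes, and precision-recall/ROC benchmark machinery (AUPR, AUROC,
    F-scores, node correctness), so the whole method can be exercised and
    evaluated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
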