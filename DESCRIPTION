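Package: mdlmotif
Title: Compression-Based Inference of Network Motif Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mines directed network motifs by lossless compression instead of
    null-model hypothesis testing. A graph is described as a reduced multigraph
    obtained by contracting induced subgraphs into supernodes; candidate motif
    sets are scored by exact codelengths under four microcanonical base models
    (Erdos-Renyi, configuration model, and their reciprocal variants), and the
    collectively most compressing motif set is selected with a stochastic greedy
    algorithm following the minimum description length principle. Includes an
    exhaustive ESU subgraph census with brute-force canonical forms for directed
    graphlets of up to five nodes, microcanonical edge-swap randomizers, a
    planted-motif generator for validation, and a classic z-score
    hypothesis-testing baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
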