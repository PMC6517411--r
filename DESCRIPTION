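Package: ictonet
Title: Model Comparison for Node-Removal Predictions in Epileptic Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates three stochastic models of seizure transitions (a
    Jansen-Rit-type neural mass model, the theta-neuron canonical model of
    the SNIC bifurcation, and a subcritical-Hopf bistable normal form) on
    binary directed networks, quantifies Brain Network Ictogenicity (BNI)
    over two-dimensional excitability-by-coupling parameter maps, computes
    Node Ictogenicity (NI) under virtual node removals, and measures the
    agreement between models' node-removal predictions with a weighted
    Kendall rank correlation.  Includes exhaustive enumeration of
    nonisomorphic weakly connected digraphs, stratified random digraph
    ensembles, and an experiment pipeline relating cross-model agreement to
    network heterogeneity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
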