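Package: dynconn
Title: Dynamic Functional Connectomes from Multi-Animal Neural Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers time-varying functional connectivity from multi-animal
    neural activity traces in three unsupervised stages: local differential
    affinities between pairs of traces (agreement of absolute smoothed
    derivatives over shared monotone intervals), non-negative canonical
    polyadic tensor decomposition of the time x animals x pair-affinities
    tensor fit by hierarchical alternating least squares, and community
    detection on the resulting affinity graphs with a weighted stochastic
    block model whose description length is minimized by a merge-split
    Markov chain Monte Carlo sampler. Ships a synthetic multi-animal trace
    simulator with planted transient circuits, a weighted benchmark-graph
    generator with planted communities, and normalized mutual information
    scoring for method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
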