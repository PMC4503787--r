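Package: ssadyn
Title: Slow-Switching Assembly Dynamics in Structured Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to predict and measure slow-switching assembly (SSA)
    dynamics in balanced excitatory-inhibitory spiking networks. Provides
    generators for structured synaptic weight matrices (clustered,
    excitatory-inhibitory co-clustered, small-world, scale-free and
    hierarchical topologies with exact conservation of average connectivity
    and weight), a leaky integrate-and-fire network simulator with
    exponential synapses, closed-form linear rate models with analytic Schur
    decompositions and stability analysis, spectral diagnostics of the
    weight matrix (eigengap detection, dominant Schur subspace,
    block-localization scoring, winner-takes-all flag), and spike-train
    metrics of assembly dynamics (spike-rate variability scores, PCA firing
    patterns, principal angles between observed and predicted subspaces).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    Matrix,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
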