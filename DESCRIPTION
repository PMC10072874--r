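Package: mpnet
Title: Multi-Plasticity Networks: Computing with Synaptic Modulations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of multi-plasticity networks (MPNs):
    feedforward networks whose input weights are multiplicatively modulated
    by a fast, exponentially decaying synapse-modulation matrix, so that
    sequential information is stored in synapses rather than recurrent
    activity. Provides the MPN variants (associative, presynaptic-only,
    postsynaptic-only, additive) and recurrent baselines (Vanilla RNN, GRU)
    with compiled batched forward/backward passes, generative
    evidence-integration tasks (delay, contextual, continuous, true-anti),
    a backpropagation-through-time training harness with the protocols for
    echo-state, sequential-learning and novel-class experiments, analytical
    approximations of the modulation dynamics, and a population-dynamics
    analysis suite (participation-ratio dimensionality, variance
    decomposition, linear decoding, cross-time decoding, readout alignment,
    activity-silence diagnostics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
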