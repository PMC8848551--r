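Package: bnsynth
Title: Probabilistic Synthetic Data Generation for Discrete Bayesian Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully probabilistic simulation framework for discrete Bayesian
    networks: random directed-acyclic-graph structure generation with exact
    model-space combinatorics, construction of conditional probability tables
    as Dirichlet-sampled simplex columns with guaranteed conditional
    dependence, exact (ancestral) forward sampling of datasets, analytic joint
    and marginal computation, Markov-blanket extraction and factored
    conditional inference, and distributional diagnostics (entropy bias of
    descendant nodes, central-limit drift, Jensen-Shannon divergence
    convergence, multinomial sample-size bounds). Intended for benchmarking
    network-inference methods in computational systems biology.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    igraph,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
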