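Package: kinseq
Title: Generative Sequence Modelling of State-to-State Molecular Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns and generates kinetically accurate state-to-state sequences of
    physicochemical systems. Provides overdamped Brownian-dynamics simulators for
    multi-well toy potentials and an active worm-like polymer chain, featurization
    (pairwise distances, radius of gyration) and autoencoder collective variables,
    K-means discretization of trajectories into token sequences, a from-scratch
    decoder-only transformer trained on those sequences, autoregressive multinomial
    generation of future states, kinetic validation via state probabilities and
    commit-time transition counts with detailed-balance diagnostics, and Markov
    state model plus LSTM baselines evaluated with the same metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
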