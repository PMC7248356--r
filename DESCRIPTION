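Package: cannets
Title: Contextually Adaptive Spiking Neural Networks as G-Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models contextually adaptive neurons and networks as G-networks
    (random neural networks): spiking units that exchange excitatory and
    inhibitory impulses at Poisson rates, with inputs partitioned into a
    driving receptive field (RF), a modulatory local contextual field (LCF)
    and a universal contextual field (UCF) encoding the external environment.
    Provides the product-form steady-state solver, an exact event-driven
    continuous-time Markov chain simulator, gradient-descent learning of the
    rate weights via implicit differentiation of the steady state, four-way
    information decomposition (entropies, conditional mutual information,
    interaction information and a weighted infomax objective), a synthetic
    multimodal audio-visual-style data generator with SNR-controlled noise,
    and ablation and contextual-modulation experiments with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
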