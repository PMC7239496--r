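Package: motifstdp
Title: Motif Expansion of Triplet Spike-Timing-Dependent Plasticity in
    Recurrent Hawkes Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analytic framework for the self-organization of recurrent
    excitatory networks under the minimal triplet model of spike-timing
    dependent plasticity (STDP). Synaptic drift is expanded in structural
    motifs whose coefficients are integrals of the excitatory postsynaptic
    current kernel against the pair and triplet learning windows, computed by
    adaptive quadrature in the frequency domain. Includes exact stationary
    rates and second- and third-order spike-train cumulants of the linear
    Hawkes network, a thinning-based spiking simulator used as a stochastic
    oracle, mean-field integration of the weight dynamics with heterosynaptic
    competition and balanced inhibition, and graph-theoretic characterization
    (clustering, efficiency, modularity, connection fractions) of the
    emergent assembly structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    ggplot2,
    igraph,
    pracma,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
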