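Package: soasim
Title: Simulated Lesion Experiments on Recurrent Network Models of the
    Sense of Agency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the sense of agency (SoA) with small
    continuous-time recurrent neural networks. Generates synthetic
    behavioral datasets for the Keio agency-attribution task (a button
    press causes an on-screen piece to jump after a variable latency and
    the subject judges agency yes/no), encodes trials as sensorimotor
    sequences, trains leaky-integrator recurrent networks by
    backpropagation through time to reproduce each synthetic subject's
    psychometric curve, and applies simulated lesions (random temporal
    delays in recurrent, input or output signal pathways, multiplicative
    state noise, reduced sigmoid gain) during the test phase. Evaluation
    utilities compute yes-rate curves, short/long-latency window
    summaries, histogram distances (mean squared error and
    Kullback-Leibler divergence), a bidirectional
    excessive/diminished-agency classification, and context-unit
    functional correlation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
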