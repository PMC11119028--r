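Package: spiketer
Title: Transfer Entropy Rate Causality Tests for Binary Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects effective (causal) connectivity between pairs of binary
    spike trains. Implements a discrete-time stochastic-neuron network
    simulator with variable-length memory (Galves-Loecherbach type), a plug-in
    estimator of the transfer entropy rate from empirical block distributions,
    and a likelihood-ratio test of no causal influence calibrated against its
    asymptotic chi-squared null distribution. Includes exact small-network
    oracles (joint transition kernel, stationary rates, exact transfer entropy
    rate) and Monte-Carlo power and size studies for the test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
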