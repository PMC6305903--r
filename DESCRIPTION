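Package: spikeval
Title: Network-Level Statistical Validation of Spiking Neural Network Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical comparison of parallel spike-train data from two
    executable implementations of a spiking neural network model. Provides a
    battery of mono-, bi-, and higher-order activity statistics (firing rate,
    inter-spike intervals, local coefficient of variation, zero-lag and
    integral cross-correlation matrices, correlation-matrix eigenstructure,
    repeated spatiotemporal spike patterns), quantitative comparison scores
    (Hedges' effect size with pooled standard deviation, two-sample t,
    Kolmogorov-Smirnov and Mann-Whitney U tests, correlation-structure
    similarity with a neuron-relabeling permutation null), and a built-in
    simulator of the Izhikevich polychronization network with a frozen-weight
    replay protocol that serves as a reproducible synthetic data source.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
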