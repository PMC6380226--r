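Package: nfmotion
Title: Hierarchical Neural-Field Simulation of Cortical Motion Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a hierarchy of laterally connected neural fields that
    self-organize direction-, pattern- and translational-flow-selective
    responses from synthetic moving stimuli (bars, edges, gratings, plaids,
    squares and random-dot fields). Lateral connections are trained with a
    temporally asymmetric Hebbian rule (a rate-based analogue of
    spike-timing-dependent plasticity) combined with divisive weight
    normalization, so that direction of motion is encoded in the recurrent
    circuitry rather than in time-lagged inputs. Provides stimulus
    generators, two-timescale training with layer-wise saturation stopping,
    topographic preference-map extraction, robustness-to-noise analyses, a
    linear perceptron readout for decoding motion direction, and plotting
    helpers for maps, activity bubbles and learning curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
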