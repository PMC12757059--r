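Package: normnet
Title: Heterogeneous Divisive Normalization in Balanced Spiking Circuit Models of Visual Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a two-layer spiking circuit model of visual cortex in
    which a linear-nonlinear-Poisson V1 front end with Gabor receptive fields
    drives a spatially ordered balanced network of exponential
    integrate-and-fire excitatory and inhibitory neurons (V4/MT). Provides
    generators for pinwheel orientation maps, Gabor and plaid stimuli with
    Ornstein-Uhlenbeck pixel noise, and naturalistic image surrogates;
    distance- and tuning-dependent connectivity with matched-in-degree and
    random control variants; a forward-Euler network integrator with
    double-exponential synapses that records spike rasters and per-type
    synaptic currents; and analysis tools for normalization indices,
    selectivity, tuning similarity, spike-count correlations, current
    covariance decompositions, contrast sensitivity, bias-corrected linear
    Fisher information with 1/N extrapolation, and mean-field manifold
    capacity of image-evoked population responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
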