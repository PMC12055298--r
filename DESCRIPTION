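Package: netews
Title: Spatial Early Warning Signals for Tipping Points on Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation of spatial early warning signals (EWSs)
    for tipping points of stochastic dynamics on networks. Provides four
    stochastic dynamics models (coupled double-well, mutualistic species,
    SIS epidemic and gene-regulatory dynamics), an Euler-Maruyama integrator,
    control-parameter sweep protocols with automatic simulation-range search
    and home-range extraction, six single-snapshot spatial EWSs (Moran's I,
    spatial standard deviation, spatial variance, coefficient of variation,
    sign-adjusted skewness and kurtosis), sign-adjusted Kendall rank
    correlation, a slope-ratio classification of EWS trajectories into
    accelerating, reversing and unsuccessful categories, and rank scoring of
    EWSs across simulation conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
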