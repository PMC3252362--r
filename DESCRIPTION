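Package: stempatterns
Title: Simulation and Spatial Analysis of Differentiation Patterns in Stem-Cell Monolayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic individual-based simulation of stem-cell
    differentiation in a confluent planar monolayer on a doubly periodic
    square domain.  Each cell carries a stemness variable that decays
    deterministically and a fate variable evolving by an Euler-Maruyama
    discretised stochastic differential equation whose supercritical
    pitchfork bifurcation is tilted by intercellular signalling, either
    diffusible morphogens (finite-volume reaction-diffusion fields advanced
    with a Douglas alternating-direction implicit scheme) or juxtacrine
    contact signalling.  Emergent two-type patterns are characterised with
    marked point-process statistics: pair correlation functions, cross- and
    same-type pair correlation functions, quadrat histograms, a pattern-scale
    estimator and a pattern-presence criterion.  Includes synthetic pattern
    generators, a multi-realisation parameter-sweep harness and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
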