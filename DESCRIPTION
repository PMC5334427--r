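Package: dcmbold
Title: Bilinear Dynamic Causal Modelling of fMRI BOLD Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for effective-connectivity analysis of block-design fMRI
    experiments with bilinear dynamic causal models (DCM).  Provides a
    stimulus simulator for a visual-motion predictability paradigm (a ball
    bouncing in a frame under specular, random and hazard-interrupted
    reflection rules), construction of nested boxcar inputs on a microtime
    grid, a balloon-Windkessel hemodynamic forward model with a
    matrix-exponential neuronal integrator, variational-Laplace model
    inversion returning posterior moments and a free-energy approximation to
    log model evidence, enumeration of factorial model spaces, fixed-effects
    Bayesian model selection with Occam's window, Bayesian parameter
    averaging with multiplicity-corrected credible intervals, and an
    end-to-end synthetic-cohort pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
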