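Package: oxyglulac
Title: Substrate-Modulated ODE Models of Cell Population Growth
Version: 0.9.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for developing and interrogating ordinary-differential-
    equation models of in vitro cell population growth modulated by
    biochemical substrates (oxygen, glucose, lactate). Enumerates a family
    of candidate models built from zero-order, first-order and
    Michaelis-Menten modulating effects, simulates well-plate culture
    experiments with replicate measurement noise, calibrates models by
    multi-start weighted nonlinear least squares (Latin hypercube + Adam +
    quasi-Newton), ranks models by information criteria, assesses practical
    identifiability by profile likelihood, computes Sobol variance-based
    sensitivity indices of culture conditions, designs sampling protocols by
    simulation-based parameter-recovery error, and studies periodic media
    refreshment over long culture horizons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
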