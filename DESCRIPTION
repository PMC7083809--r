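Package: neurofem
Title: Finite-Element Forward and Hierarchical Bayesian Inverse Modelling
    for EEG and EIT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-compartment tetrahedral head-mesh generation from
    triangulated tissue surfaces, finite-element assembly of EEG and
    linearized electrical impedance tomography (EIT) lead fields with the
    complete electrode model, divergence-conforming (H(div)) dipole source
    stencils with position-based optimization, and hierarchical Bayesian
    inversion: iterated alternating sequential (IAS) MAP estimation with
    gamma or inverse-gamma hyperpriors, region-of-interest and randomized
    multiresolution-decomposition variants, and a Gibbs-sampler conditional
    mean. Includes layered-sphere phantom generators, an analytic
    dipole-in-sphere oracle, and parcellation-based region time-series
    analysis with dynamic time warping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
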