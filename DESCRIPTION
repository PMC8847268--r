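Package: edlwave
Title: Equivalent Double Layer Inverse Electrocardiography with a
    His-Purkinje Multi-Wave Initial Estimate
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Non-invasive imaging of ventricular activation from body
    surface potential maps (BSPM) using the equivalent double layer (EDL)
    source model.  Provides a boundary element method (BEM) volume
    conductor, a fastest-route activation simulator with elliptical
    anisotropy and a sub-endocardial velocity boost, two initial
    estimators (a nine-region His-Purkinje multi-wave search over all 511
    foci subsets, and a baseline multi-focal additive search), a
    Levenberg-Marquardt refinement of nodal activation times with
    surface-Laplacian regularization, evaluation metrics (BSPM
    correlation and relative difference, inter-map statistics,
    triangulation conduction velocity, breakthrough counting,
    electro-anatomical map alignment), and a synthetic biventricular
    torso phantom for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
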