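Package: swmtools
Title: Surface-Based Profiling of Superficial White Matter Microstructure
Version: 0.1.0
Authors@R:
    person("SWM", "Tools Developers", email = "swmtools@example.org",
           role = c("aut", "cre"))
Description: Laplace-field guided placement of sub-cortical surfaces beneath
    the gray/white matter interface, depth-wise intensity profiling of
    co-registered feature volumes with statistical moments and outlier
    repair, microstructural profile covariance (MPC) matrices with diffusion
    map embedding gradients, and spatially-aware association statistics
    (spin permutation tests, LOWESS trends) against cortical geometry and
    connectivity. Includes analytic slab and spherical-shell phantoms with
    known Laplace solutions, planted depth profiles, and synthetic
    connectomes so that every pipeline stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    xml2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
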