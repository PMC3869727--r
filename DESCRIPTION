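Package: morphomech
Title: Mechanochemical Pattern Formation on Deforming Tissue Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulator for spontaneous pattern formation in closed embryonic
    tissue sheets driven by a positive feedback loop between tissue curvature
    and morphogen expression. Tissue mechanics follow a gradient flow of a
    modified Helfrich bending energy with morphogen-dependent spontaneous
    curvature under local area incompressibility; the morphogen obeys a
    surface reaction-diffusion equation with linear degradation and
    curvature-gated Michaelis-Menten production. Provides a closed-curve and
    a triangulated closed-surface backend, discrete differential operators,
    exact discrete shape gradients, a semi-implicit coupled integrator, a
    numerical linear-stability oracle, pattern (patch) quantification,
    parameter sweeps, virtual pull/press experiments, and VTK/OBJ/CSV input
    and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    methods,
    igraph,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
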