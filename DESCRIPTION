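Package: lobulesim
Title: Lattice Simulation of Blood Flow and Drug Metabolism in Hepatic Lobules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Generates two- and three-dimensional hexagonal liver-lobule
    sinusoid morphologies with a sequential diffusion-limited aggregation
    recipe, solves steady Darcy pressure and flow on the labeled lattice with
    a central portal inlet and six hepatic-vein corner outlets, and simulates
    transient convection-diffusion-reaction transport of paclitaxel and its
    hydroxylated metabolite, including oxygen-gradient-driven zonation of the
    metabolic rate. Includes unit conversions between SI and simulator working
    units, production-curve bookkeeping with mass-balance closure, plain-text
    morphology containers, CSV production output and legacy VTK snapshot
    export.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
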