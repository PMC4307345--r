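Package: bioheatmfs
Title: Meshless Operator-Splitting Solver for Transient Nonlinear Bioheat
    Transfer in Skin Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves the transient Pennes bioheat equation in a
    two-dimensional rectangular skin-tissue domain with a
    temperature-dependent blood perfusion rate (constant, linear or
    exponential in temperature). Each time step combines a second-order
    Adams-Bashforth extrapolation of the nonlinear perfusion source with a
    second-order Adams-Moulton (trapezoidal) treatment of diffusion, which
    reduces the update to a modified Helmholtz problem. That problem is
    solved meshlessly: thin-plate-spline dual-reciprocity particular
    solutions handle the nonhomogeneous term and the method of fundamental
    solutions with the Laplace kernel handles the homogeneous part. The
    package includes an independent Crank-Nicolson finite-difference
    reference solver, closed-form steady solutions for validation, and
    post-processing for centerline profiles, steady-state timing,
    multi-curve intersections and perfusion-coefficient sensitivity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
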