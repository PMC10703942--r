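Package: respmech
Title: Hyperelastic Lung Mechanics: Material Calibration, Quasi-Static
    Breathing Simulation and Respiratory Validation Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale toolkit for biomechanical modelling of lung
    respiration. Fits isotropic hyperelastic constitutive models (Ogden,
    polynomial, reduced polynomial, van der Waals) to nominal stress-strain
    test curves by relative least squares, screens Drucker stability, and
    ranks a candidate roster. Provides a synthetic half-ellipsoid lung
    phantom with named boundary sets, a quasi-static total-Lagrangian
    nonlinear finite-element solver on linear tetrahedra with follower
    transpulmonary pressure and a piecewise-linear breathing schedule, and
    the landmark-displacement, slice-area and volume validation metrics
    used to compare simulated expiration against reference imaging.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
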