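Package: viscogpr
Title: Physics-Informed Gaussian Process Surrogates for Visco-Hyperelastic
    Constitutive Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds data-driven constitutive models for strain-rate-sensitive
    (visco-hyperelastic) soft materials. The second Piola-Kirchhoff stress is
    decomposed into volumetric, isochoric hyperelastic, and isochoric viscous
    overstress components, each expressed as a linear combination of an
    isotropic integrity basis of the right Cauchy-Green tensor and its rate.
    Per-point least-squares solves convert stress-strain(-rate) data into
    invariant/coefficient training sets, and Matern-3/2 Gaussian process
    regression (standard, and inequality-constrained to enforce non-negative
    viscous dissipation) learns the coefficient functions. Includes finite-
    strain kinematics utilities, phenomenological material laws and loading
    protocols for generating synthetic datasets, conventional-model
    calibration baselines, and error-metric reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
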