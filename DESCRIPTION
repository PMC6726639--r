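Package: valvefsi
Title: Constitutive-Law Fitting and Desk-Scale Fluid-Structure Interaction
    for Heart-Valve Biomechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transversely isotropic hyperelastic constitutive models for
    mitral-valve leaflets (three strain-invariant laws) and chordae
    tendineae (neo-Hookean and exponential), with exact incompressibility
    and a tension-only collagen-fiber switch.  Includes inverse parameter
    estimation from biaxial and uniaxial stretch-stress data by bounded
    multi-start Levenberg-Marquardt least squares, goodness-of-fit
    reporting (R-squared, average error), a synthetic-experiment generator
    emulating planar biaxial leaflet and uniaxial chordae tensile tests,
    and a two-dimensional immersed-boundary/finite-element demonstrator of
    valve dynamics in a pressure-driven channel, together with hemodynamic
    evaluation metrics (transvalvular flow rate, closure regurgitation
    volume, orifice area, peak jet velocity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
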