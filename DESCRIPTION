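Package: chmito
Title: Cahn-Hilliard Phase-Field Simulation of Mitochondrial Inner-Membrane Morphology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element simulator for phase separation of the mitochondrial
    inner membrane and fluid matrix, modelled by the dimensionless Cahn-Hilliard
    equation on disk, ellipse, sphere and ellipsoid domains. Calcium phosphate
    granules are represented as volume-excluded holes whose boundaries pin the
    order parameter. Includes a mixed two-field theta-method solver with Newton
    iteration, closed-form linear-stability results with an independent
    finite-difference growth-rate oracle, free-energy and mass diagnostics, and
    morphometric analysis (phase fractions, interface length, connected
    components, spectral characteristic length, granule halo composition) of the
    resulting cristae-like patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
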