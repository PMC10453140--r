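Package: rfdry
Title: Coupled Heat-Mass Transfer Simulation of Hot-Air and Radio-Frequency
    Assisted Drying of Fruit Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Finite-volume simulator for convective hot-air drying of thin
    cylindrical fruit (jujube) slices with optional radio-frequency (27.12
    MHz) volumetric heating. Couples an axisymmetric conduction equation
    with a Fickian moisture-diffusion equation through temperature- and
    moisture-dependent material properties (specific heat, thermal
    conductivity, complex permittivity) and convective-evaporative boundary
    conditions. Includes a quasi-static electromagnetic field solver
    (layered-capacitor closed form and 2-D complex Laplace), Dincer-model
    drying-kinetics estimators (lag factor, drying coefficient, mass Biot
    number, effective diffusivity, transfer coefficients), staged drying
    schedules, electrode-voltage calibration, comparison metrics, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
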