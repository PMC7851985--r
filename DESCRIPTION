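Package: veincuff
Title: Impedance Simulation of a Cuff-Electrode Instrumented Venous Segment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static finite-volume simulation of two-electrode bioimpedance
    spectroscopy of a saline-perfused venous segment instrumented with a cuff of
    surface electrodes and an axial ground wire. Builds parametric cylindrical
    models, solves the complex conduction problem over a 10 Hz to 1 MHz sweep,
    and post-processes lead-field sensitivity, volume impedance density and
    power-loss density to decompose the measured impedance into per-region
    contributions as a function of electrode number, radius, excitation mode
    and position. Includes analytic phantoms (slab, coaxial, bilayer) with
    closed-form oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
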