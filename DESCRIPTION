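Package: bwsle
Title: Single-Parameter Bragg-Williams Modeling of Solid-Liquid Equilibria
    in Binary Eutectic Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts liquidus curves of binary eutectic mixtures from
    pure-compound melting data (melting temperature and enthalpy of fusion)
    plus a single interaction parameter zw, using the Bragg-Williams
    (regular-solution) lattice model. Provides the ideal
    (Schroeder-van Laar) and Bragg-Williams liquidus branches in closed
    form, eutectic-point location, estimation of zw from experimental
    melting points (per point with the two-branch rule, and by grid-search
    fit minimizing the average absolute deviation), analytic propagation of
    uncertainties in the measured temperature and in the pure-compound
    melting data, inverse-variance weighted averaging of per-point
    estimates, a seeded synthetic-data generator with a parameter-recovery
    harness, CSV input/output, and a command-line front end. Ships a
    packaged registry of thermodynamic data for thirteen compounds commonly
    used in type V deep eutectic solvents.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
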