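Package: tenposim
Title: Multiphysics Simulation of Immunomagnetic Capture on Magnetic
    Nanopore Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates the capture of magnetically labeled extracellular
    vesicles (EVs) on track-etched magnetic nanopore (TENPO) membranes.
    Combines a closed-form magnetostatic model of a saturated NiFe film
    pierced by a cylindrical pore (Babinet sheet-minus-disk superposition,
    evaluated with Bulirsch elliptic integrals), a semi-analytic laminar
    flow field through the pore unit cell with a numerical axisymmetric
    Stokes reference solver, and overdamped Lagrangian tracking of
    EV-nanoparticle complexes under magnetophoretic and viscous drag
    forces.  Provides the canonical in-silico experiments: capture-rate
    grids for strongly- versus weakly-tagged EVs across pore diameter,
    flow rate and membrane count, force-ratio diagnostics, and
    clogging/occlusion impact studies, with YAML configuration and CSV
    result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    pracma,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
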