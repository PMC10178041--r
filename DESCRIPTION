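Package: drypod
Title: Two-Component Heat and Mass Transfer Simulation of Peanut Pod
    Convective Drying
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates thin-layer convective drying of peanut pods as a
    two-component (shell plus kernel) body of revolution.  A 2D
    axisymmetric finite-element solver integrates coupled transient heat
    conduction and Fickian moisture diffusion with convective (Robin)
    boundary conditions, region-wise effective diffusivities, and
    moisture-dependent thermal properties.  Companion tools evaluate hot
    air property correlations and Nusselt/Sherwood transfer coefficients,
    estimate effective moisture diffusivity from drying curves by the
    log-slope slab inverse method, synthesize drying curves from the slab
    series solution, and compute drying-rate and moisture/temperature
    field summaries.  Simulations export component-averaged drying curves
    (CSV), field snapshots (VTU), and run metadata (JSON).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
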