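Package: assocfit
Title: Protein Self-Association Equilibria from Sedimentation Equilibrium,
    Thermophoresis and Calorimetry, with Structural Interface Auditing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying protein monomer-homodimer (and higher
    order) self-association. Implements mass-action species solvers,
    global fitting of multi-speed multi-loading analytical
    ultracentrifugation sedimentation-equilibrium data with mass
    conservation and parametric Monte Carlo confidence intervals,
    microscale thermophoresis dose-response models (1:1 and trace-label
    self-association), the one-site isothermal titration calorimetry
    injection-heat model with thermodynamic derivation, and
    structure-based interface analysis (Shrake-Rupley solvent-accessible
    surface area, buried interface area, core/rim residue classification,
    linker-reach feasibility, declarative constraint auditing). Seeded
    synthetic-data generators emulate the instrument designs so every
    stage can be exercised without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
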