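Package: crispri
Title: Equilibrium Modelling and Characterization of CRISPRi Logic Inverters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative characterization of CRISPR
    interference (CRISPRi) logic inverters in engineered bacteria. Solves
    the steady-state mass-action binding equilibrium of dCas9, single
    guide RNA (sgRNA) and target promoter DNA by damped fixed-point
    iteration (with an independent nested-bisection solver for
    verification), sweeps transfer curves and locates repression switch
    points, reduces 96-well microplate absorbance/fluorescence kinetics
    to growth rates and per-cell synthesis rates, fits Hill-equation
    stage models to transfer curves and composes them into NOT-gate
    cascades and hybrid NOR gates, and generates synthetic plate-reader
    and transfer-curve data with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    lhs,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
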