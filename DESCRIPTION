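Package: hsycalcium
Title: Calcium and IP3 Oscillation Modelling in HSY Salivary Duct Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Deterministic modelling of coupled cytosolic calcium and
    inositol trisphosphate (IP3) oscillations in HSY cells, a human salivary
    duct cell line. Implements a six-variable ordinary differential equation
    model coupling endoplasmic-reticulum and plasma-membrane calcium fluxes,
    a two-mode (park/drive) IP3-receptor gating submodel with a receptor
    microdomain, and calcium-dependent IP3 production by phospholipase C.
    Provides virtual experimental protocols (agonist steps, closed-cell
    simulation, calcium-free medium, photorelease of caged IP3 as pulses or
    continuous uncaging, and PLC inhibition), spike-train analysis of the
    resulting trajectories (periods, frequencies, amplitudes, calcium-to-IP3
    peak delays, termination times), and a generator of synthetic
    fluorescence-like traces with known ground truth for validating the
    trace analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
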