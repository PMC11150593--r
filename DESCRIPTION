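Package: co2challenge
Title: Inspired-CO2 Targeting by Flow-Proportional Admixture: Controller,
    Closed-Loop Respiratory Simulator and Breath-by-Breath Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and evaluating inspired-CO2 gas challenges
    of the kind used in cerebrovascular-reactivity imaging. Implements a
    piecewise stimulus-protocol engine with safety clamping, the
    mass-balance controller that admixes a flow-proportional stream of
    concentrated CO2 into the respiratory gas (and a three-gas reservoir
    mixer reference), a closed-loop simulator of a ventilated test lung or
    a spontaneously breathing subject with circuit gas transport, a dynamic
    alveolar compartment and a delayed sidestream gas analyzer, plus
    breath-phase detection, inspired and end-tidal gas extraction, binned
    aggregation with bootstrap confidence intervals, and per-stimulus
    target-deviation reporting with transition removal.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
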