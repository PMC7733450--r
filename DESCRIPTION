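Package: pureregen
Title: Chemostat Simulation and Analysis of Self-Regenerating Cell-Free Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models continuous cell-free transcription-translation (PURE)
    reactions in microfluidic chemostats that regenerate their own protein
    components from DNA templates. Provides a resource-limited ODE model of
    coupled T7 RNA polymerase and reporter expression (and a shared-enzyme
    alternative), an event-driven dilution engine with segment-based feed
    composition and three-phase experiment protocols, trace analysis metrics
    (yield, robustness, SR/PC ratio, washout-peak detection, Pareto fronts),
    steady-state DNA dose-design calculators, and a seeded synthetic-data
    generator with least-squares parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
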