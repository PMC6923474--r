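Package: nmdarblock
Title: Kinetics of NMDA Receptor Open-Channel Block and
    Calcium-Dependent Desensitization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of whole-cell NMDA receptor currents
    under voltage-dependent open-channel block and calcium-dependent
    desensitization, as produced by amphiphilic cationic blockers such as
    amitriptyline.  Provides a deterministic five-state master-equation
    simulator of macroscopic currents under timed solution-exchange
    protocols, readers and writers for a plain-text trace container,
    steady-state and exponential-relaxation measurements, Hill
    concentration-inhibition fits, rate-constant estimation from
    relaxation time constants, Woodhull voltage-dependence and
    calcium-dependence models, a composite IC50(Vm, [Ca2+]) surface,
    trapping-protocol analysis with block-mode classification, and the
    accompanying group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
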