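Package: co2reg
Title: Closed-Loop Simulation of Low-Cost Incubator CO2 Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Software model of a low-cost CO2 setpoint controller for
    microbial incubators, together with the plant it regulates. Provides a
    well-mixed chamber gas mass-balance model, a first-order lagged NDIR
    sensor model with range clipping and fault injection, three control
    laws (threshold bang-bang, timed-activation pulse control, and discrete
    PID with a proportional-valve current map), the firmware safety state
    machine (pause button, stuck-sensor freeze, environmental leak latch),
    setpoint calibration rules with persisted settings, and a closed-loop
    scenario runner with stability metrics and strategy comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: graphics, jsonlite, stats, tools, utils
Suggests: testthat (>= 3.0.0), yaml, optparse, deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
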