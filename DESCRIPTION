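Package: optoloop
Title: Desk-Scale Simulation and Control of Optogenetic Gene-Expression
    Feedback Loops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulator and control library for automated optogenetic
    feedback regulation of gene expression and growth in continuous
    bacterial cultures driven by the green/red light-switchable CcaS/CcaR
    two-component system.  Provides the linear mRNA/immature/mature
    fluorescent-protein expression model in raw and fold-change
    coordinates with a Hill dose-response input map, synthetic
    flow-cytometry event generation and gating, gain-scheduled
    proportional-integral and adaptive model-predictive controllers with
    joint state-and-parameter particle filtering, exact zero-order-hold
    discretization with input delay and disturbance augmentation,
    maximum-likelihood model calibration, turbidostat-based growth-rate
    estimation and control, and a scenario harness that replays reference
    tracking and disturbance-rejection experiments in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
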