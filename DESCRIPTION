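Package: cuffsim
Title: Cuff-Vasculature Interaction Simulation and Sensitivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lumped-parameter simulation of the arm circulation distal to an
    inflating blood-pressure cuff. A nonlinear tube law couples arterial
    cross-sectional area to transmural pressure; the occluded brachial
    segment is a transmural-pressure-dependent Poiseuille resistance feeding
    a two-compartment (arterial/venous) RC circuit, with venous collapse
    under the cuff. From simulated inflations the package derives per-beat
    pulse transit time (PTT) and pulse arrival time (PAT) responses via the
    Bramwell-Hill relation, extracts six scalar response metrics of the
    distal filling effect, and quantifies parameter influence with
    variance-based Sobol sensitivity analysis on a quasi-random Saltelli
    design. Includes virtual experiments (cuff length, inflation rate,
    blood-pressure dependency regressions) and a toolkit that synthesizes
    ECG/ABP/PPG-like recordings to exercise fiducial-based interval
    measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
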