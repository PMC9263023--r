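Package: hemocontrol
Title: Closed-Loop Hemodynamic Critical-Care Controller and Synthetic
    Ischemia-Reperfusion Patient Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based closed-loop critical-care controller that titrates
    norepinephrine and delivers weight-based crystalloid boluses from 1-minute
    averaged mean arterial pressure (MAP) and central venous pressure (CVP),
    together with a lumped-parameter synthetic swine model of post-reperfusion
    vasodilatory shock, an experiment choreographer that replays a
    hemorrhage/aortic-occlusion/transfusion/wean timeline, and time-in-range
    metrics (1-minute binning, pressure-band proportions, intervention
    statistics, median/IQR cohort summaries). The full loop can be simulated,
    replayed against recorded vitals, and evaluated without animal experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Depends:
    R (>= 4.1)
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
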