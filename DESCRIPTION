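Package: timingnet
Title: Interval Timing and Speed-Accuracy Trade-Off in Coupled Cortical
    Circuit Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based spiking simulations and analytical reductions
    of a local cortical circuit model of interval timing. A ring network of
    leaky integrate-and-fire pyramidal cells and interneurons produces
    climbing activity whose threshold-crossing time estimates temporal
    intervals, controlled by the strength of NMDA receptor conductance. The
    package implements the interval-estimation task with trial-to-trial
    learning and start/stop control pulses, a coupled-circuit decision task
    in which the timing circuit gain-modulates an identical decision circuit
    to trade speed for accuracy, a Wilson-Cowan-type neural-field reduction
    with steady-state and eigenvalue analysis of the climbing regime, and
    Ornstein-Uhlenbeck first-passage theory explaining the scalar property
    (Weber's law) of the interval estimates. Includes spike-density
    functions, Gaussian profile fits, interspike-interval statistics with
    Hartigan's dip test, and summary statistics with bootstrap confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
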