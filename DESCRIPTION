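Package: ringcompass
Title: Ring-Attractor Simulation and Circular Analysis of the Fly Head-Direction System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates the Drosophila head-direction (compass) circuit as a
    ring attractor of EPG neurons receiving inhibitory, Hebbian-plastic input
    from ring (ER) neurons that convey visual and wind cue position. Provides
    the closed-loop heading-trajectory generator, cue schedules for intensity
    sweeps, two-cue conflict shifts, cue combination and gain inversion, and a
    circular-statistics analysis pipeline: von Mises bump fitting with a
    goodness-of-fit gate, vector-strength heading-encoding accuracy, bump and
    behavioural preference indices, remapping indices, and a Bayesian
    linear-circular regression of offset change on cue conflict with von Mises
    noise. A synthetic-recording generator emulates imaging-like population
    data so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
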