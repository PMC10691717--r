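Package: fishschool
Title: Burst-and-Coast Modelling of Schooling Fish in a Circular Arena
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven modelling of intermittent burst-and-coast swimming in
    small schooling fish (rummy-nose tetra) confined to a circular arena, across
    light (illuminance) conditions. Provides an asynchronous kick-event
    simulator with spontaneous heading noise, wall avoidance, and pairwise
    attraction and alignment interactions restricted to the most influential
    neighbors; collective observables (dispersion, polarization, milling,
    nearest-neighbor and wall distances); a preprocessing pipeline for tracker
    output (pixel conversion, identity resolution, activity filtering,
    Savitzky-Golay kick segmentation, mirror symmetrization); and a
    reconstruction procedure that recovers the interaction functions and their
    parameters from kick-level data, enabling closed-loop parameter recovery on
    simulated trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
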