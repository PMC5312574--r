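Package: lickometry
Title: Operant Licking Schedules, Virtual-Rat Simulation and Lick
    Microstructure Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A software re-implementation of an open-source operant
    lickometer system for rodents. Provides deterministic state machines
    for fixed-ratio, variable-ratio and progressive-ratio reinforcement
    schedules with post-reward timeouts and cue-light logic; a session
    controller driven by timestamped event streams (licks on active and
    inactive spouts, motion, RFID scans); a seeded virtual-rat generator
    that emulates cluster-structured rodent licking so the whole pipeline
    is testable without animals or hardware; lick-microstructure analysis
    (inter-lick-interval cluster segmentation, cluster sizes, cumulative
    records, activity binning, active-vs-inactive spout statistics); and
    an environmental-monitoring data model with device comparison,
    light-cycle transition detection and changepoint estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tibble,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
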