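Package: flyclimb
Title: Multibeam Climbing-Assay Analysis for Fly Locomotor Phenotyping
Version: 0.1.0
Authors@R: person("flyclimb", "maintainers", email = "maintainers@flyclimb.org",
    role = c("aut", "cre"))
Description: Tools for analysing negative-geotaxis climbing assays recorded with
    vertical multibeam activity monitors that report a fly's position in 3 mm
    bins once per second. Parses monitor recordings into per-fly trajectories,
    segments climbing events and descents, computes the standard per-fly
    climbing metrics (climbs to top, complete ascents, dwell times, climbing
    velocities), classifies descents into drops versus descending climbs by
    velocity thresholds, and runs the group statistics used in locomotor
    pharmacology studies (two-way ANOVA with Tukey HSD, Fisher's exact test,
    the Marascuilo multiple-proportion procedure, and therapeutic-window
    analysis of binary flight outcomes). Includes an agent-based fly simulator
    that emits 1 Hz, 3 mm-quantized trajectories with ground-truth event logs
    for end-to-end validation, and a command-line interface wiring the full
    simulate - metrics - classify - stats pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
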