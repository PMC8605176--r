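Package: envshift
Title: Mean Firing Rate Change Analysis for A-B-A' Environmental Manipulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for extracellular recordings collected under an
    A-B-A' (baseline, manipulation, return-to-baseline) session design in
    freely foraging rodents. Classifies neurons whose mean firing rate (MFR)
    systematically changes during the middle manipulation session using
    block-wise Kruskal-Wallis tests with Scheffe-type post hoc comparisons,
    builds occupancy-normalized 2D spatial ratemaps, characterizes linear
    speed tuning with a uniform-versus-linear F-test, and runs population
    vector correlation analyses on 400 ms binned rate vectors. Includes an
    inhomogeneous-Poisson foraging/spiking simulator with known ground truth
    so every stage is testable end to end without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
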