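Package: sptseg
Title: Diffusion-Mode Segmentation of Single-Particle Trajectories with a
    Back-Propagation Neural Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates two-dimensional membrane diffusion trajectories
    (Brownian, confined, directed and composites thereof, with optional
    static positioning noise), computes mean square displacement (MSD)
    curves and fits the standard free, directed and confined diffusion
    models, trains a three-layer back-propagation neural network on
    normalized MSD curves of short trajectory windows, calibrates
    run-length-dependent false-positive thresholds on Brownian null
    ensembles, and segments arbitrary trajectories into Brownian,
    confined and directed portions with per-segment diffusion
    parameters (D, confinement diameter L, drift speed V).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
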