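Package: skelfit
Title: Markerless 3D Motion Capture of Monkeys by Skeleton-Model Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markerless three-dimensional motion capture for freely moving
    macaques from multi-view depth cameras. Merges per-camera depth and color
    frames into a colored, normal-bearing surface point cloud, fits an
    articulated 23-sphere skeleton model into the cloud by a physics-style
    simulation of attraction, repulsion and face-color attraction forces run
    to steady state, tracks the model across video frames with a reproducible
    correction interface and loess smoothing, and derives behavioral events
    (bar crossing, jumping, crawling) and kinematic parameters (path length,
    walking speed, head-rotation speed) from the resulting trajectories. A
    built-in articulated-phantom renderer emulates the four-camera rig so the
    entire pipeline is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
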