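Package: rheopipe
Title: Rheotaxis Analysis of Larval Zebrafish in Radial Suction Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify rheotaxis of freely swimming larval zebrafish in
    a radial suction-flow assay. Provides a ground-truthed synthetic session
    generator and frame renderer, image segmentation by background subtraction,
    posture estimation from image moments (equivalent ellipses, body angle and
    signed curvature), identity-preserving trajectory linking, swim-bout
    detection from the curvature trace with a Stokes-drag impulse-response fit,
    simulation of passive reorientation of inert larvae in the sink flow, and
    population-level behavioral statistics (circular variance of orientation,
    counterflow-swim-sequence labeling, kernel density estimates, radial
    position-holding profiles and distribution tests). All user-facing
    functions take and return data frames so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    zoo
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
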