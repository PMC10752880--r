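Package: phasetrack
Title: Automated Cell Migration Tracking in Phase-Contrast Time-Lapse Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free tracking of migrating cells in phase-contrast
    time-lapse image series. Corrects lateral frame misalignment with
    sub-pixel registration, segments dark cell nuclei by an adaptive
    grey-level limit, splits touching cells at concave boundary points,
    links detections across frames by greedy least-displacement matching
    with two-frame gap repair, and computes standard migration measures
    (velocity, accumulated and Euclidean distance, directness, forward
    migration index) per track, per time step and per video. Includes a
    seeded synthetic video generator with exact ground-truth trajectories
    for end-to-end verification, and cross-method trajectory comparison
    tools (track matching, distance distributions, Bland-Altman velocity
    agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    ggplot2,
    generics,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
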