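Package: afmkin
Title: Multi-Segment Foot Kinematics with the Amsterdam Foot Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes multi-segment foot and ankle kinematics from labeled 3D
    marker trajectories using the Amsterdam Foot Model (AFM): anatomical and
    technical segment coordinate systems for shank, hindfoot, midfoot,
    forefoot (optionally split medial/lateral) and hallux, static-trial
    calibration, Cardan (z-x'-y'') joint angle decomposition, medial
    longitudinal and transverse tarsal arch planar angles, gait event
    detection with stride normalization and range of motion, virtual
    marker-misplacement sensitivity analysis, soft-tissue-artifact style
    two-configuration comparisons, and inter-/intra-tester repeatability
    statistics (sigma, SEM). Ships a synthetic anthropometric template foot
    and rigid-segment gait generator with ground-truth angles and events so
    the whole pipeline is testable without laboratory data. Reads and writes
    TRC and wide CSV marker trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
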