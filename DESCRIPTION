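Package: lungesyn
Title: Muscle Synergies and Joint Kinetics of Balance-Recovery Lunges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for perturbed and unperturbed lunge trials:
    gait-event segmentation (force-plate touchdown, foot acceleration/jerk
    lift-off, energy-statistic change-point steady state), surface EMG
    envelope processing and coactivation indices, muscle-synergy extraction
    by Gaussian non-negative matrix factorization with multiplicative
    updates, spatiotemporal synergy metrics (center of activity, full width
    at half maximum, primitive overlaps), and sagittal-plane link-segment
    inverse dynamics. Ships a synthetic-trial generator with known ground
    truth so every stage can be validated against a recoverable answer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
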