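Package: serialfoe
Title: Serial Dependence Between Form and Motion Focus-of-Expansion Percepts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for serial-dependence experiments
    in which observers alternately judge the focus of expansion of a Glass
    pattern (form orientation) and of a translational optic-flow field (motion
    direction). Provides a configurable synthetic observer that generates
    alternating form/motion trial sequences with center bias and an attractive
    pull from the previous trial's other-modality feature; geometric
    constructors for the Glass-pattern and dot-cloud displays with verifiable
    focus-of-expansion invariants; multi-factor trial-history regressions of
    the perceived angle on the current stimulus and the previous and next
    other-modality stimuli, with coefficient inference; and a shuffle-and-split
    permutation test for differences in serial-dependence coefficients between
    stimulus-reliability (dot-density) conditions.
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
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
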