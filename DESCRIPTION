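Package: bowkin
Title: Kinematics of Bow-Direction Reversals in Cello Bowing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing motion-capture recordings of cello bowing,
    from raw marker trajectories to bow-reversal metrics, proximal-to-distal
    arm-coordination measures, and mixed repeated-measures ANOVA group
    statistics. Includes zero-phase Butterworth preprocessing, virtual
    joint-centre estimation, cello-centred coordinate transforms, velocity
    zero-crossing reversal detection with rule-based acceleration peak
    counting, and a synthetic kinematic generator that emulates expert-like
    and novice-like bowing with known ground truth, so the entire pipeline
    can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    yaml,
    signal,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
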