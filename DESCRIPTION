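Package: dyadsmile
Title: Smile Detection and Positive Emotional Mimicry Scoring for Dyadic
    Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies positive emotional mimicry in face-to-face dyadic
    interactions from automated facial action-unit (AU) intensity time
    series (OpenFace 2.2 CSV dialect). Provides readers and cleaners for
    AU tracker output, within-subject baseline z-standardization, a
    composite positive-expression score ((AU12 + AU06)/2 - AU04),
    zero-phase Butterworth smoothing, threshold-based smile detection
    with interval merging and manual-edit overlays, shared-smile matching
    within a temporal window, mimicry-score and smile-ratio metrics, a
    synthetic dyad simulator with known ground truth, and group-level
    mixed-model comparisons with Tukey-adjusted contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
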