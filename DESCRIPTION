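Package: psycompare
Title: Simulated Comparison of Adaptive and Constant-Stimuli
    Psychophysical Procedures
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulates yes/no discrimination experiments and compares the
    three classical ways of estimating a psychometric function from them.
    Provides a lapse-corrected cumulative-Gaussian psychometric model with
    maximum-likelihood fitting (point of subjective equality and
    just-noticeable difference extraction), a QUEST+ Bayesian adaptive
    procedure with expected-posterior-entropy stimulus placement, randomly
    interleaved simple up-down staircases, and method-of-constant-stimuli
    designs for three experiments (size, orientation, and temporal-order
    judgments). Seeded simulated-observer cohorts replace human
    participants, and method-comparison analytics (Bland-Altman limits of
    agreement, normality-gated correlations, the robust Sn outlier screen,
    and a repeated-measures learning analysis) quantify how well the
    procedures agree.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
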