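Package: typeage
Title: Brain-Age Estimation from Smartphone Keystroke Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for estimating a behavioral brain-age
    biomarker from passively collected smartphone keystroke metadata.
    Raw keypress event streams are tokenized into typing sessions with a
    5-second gap rule, summarized into thirty kinematic and regularity
    features per subject (including sample entropy of session-level
    series), and used to train tuned random-forest age-regression models.
    Per-subject prediction errors (the brain-age gap) are contrasted
    between groups screening positive and negative on a bipolar-disorder
    screening instrument, with rank-based tests and Holm-Bonferroni
    multiplicity control. Model interpretation uses out-of-bag permutation
    importance and first- and second-order Accumulated Local Effects. A
    synthetic-cohort simulator generates keystroke streams with
    controllable age signals and a brain-age offset so the full pipeline
    is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    randomForest,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
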