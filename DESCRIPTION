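Package: dichoptr
Title: Simulation and Analysis of Dichoptic Stereoacuity and Interocular
    Suppression Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing dichoptic psychophysics
    experiments on stereoacuity and interocular suppression in amblyopia.
    Provides simulated observers with known psychometric and suppression
    parameters, an interleaved adaptive-staircase engine (two-down/one-up
    and one-down/one-up) for 4AFC stereo threshold measurement, maximum
    likelihood cumulative-normal psychometric fitting with a 62.5 percent
    correct threshold criterion, dichoptic-letter contrast-ratio estimation,
    binocular-function scoring, CR-proportional contrast rebalancing,
    random-dot stereogram rendering with log-Gabor micropatterns, and the
    repeated-measures statistical pipeline (Greenhouse-Geisser corrected
    ANOVA, Bonferroni post hoc tests, paired t-tests on log thresholds,
    multiple regression) used to analyse such studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    png,
    withr
Suggests:
    testthat (>= 3.0.0),
    car,
    yaml
Config/testthat/edition: 3
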