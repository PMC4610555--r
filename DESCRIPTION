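Package: gaitphase
Title: Gait-Phase Detection from Wearable Gyroscopes with Continuous Hidden Markov Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Segments pediatric gait into two-, four- and six-phase vocabularies from
    sagittal angular velocity of foot and shank using continuous Gaussian-emission
    left-right hidden Markov models. Provides footswitch-based reference phase
    partitioning, subject-specific and standardized-parameter (inter-subject) training
    protocols, scalar and distributed (two-signal fusion) classifiers, a
    tolerance-windowed sensitivity/specificity evaluation with the ROC goodness index,
    and a synthetic gait cohort generator so the full study design can be exercised
    without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
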