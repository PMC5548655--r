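Package: probcal
Title: Calibration of Classifier Scores to the Probability of Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates binary-classifier scores on arbitrary scales to the
    probability-of-disease scale by three methods: a parametric sigmoid fit
    (Platt scaling with regularized targets, Newton optimization, and
    delta-method standard errors), a semi-parametric latent proper-binormal
    likelihood-ratio model fitted by multinomial maximum likelihood on
    truth-state-run bins, and a non-parametric isotonic regression via the
    pool-adjacent-violators algorithm with balanced-bootstrap percentile
    confidence intervals. Includes score-model simulators, true-posterior and
    theoretical Brier-score computations, prevalence rescaling, and a
    simulation-and-evaluation suite comparing the three methods by confidence
    interval width, mean squared error against the true posterior, and Brier
    score under resubstitution and independent evaluation.
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
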