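Package: metagrt
Title: General Recognition Theory Analysis of Metamemory Confidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fits bivariate-Gaussian general recognition theory models with
    individual differences (GRT-wIND) to joint metacognitive-state and
    confidence response counts from two-stage metamemory experiments, in which
    tip-of-the-tongue (TOT) or feeling-of-knowing (FOK) judgments precede a
    recognition decision and a post-decision confidence rating. From a fitted
    model the package derives type-2 sensitivity-versus-metacognition (SvM)
    curves: the relative likelihood of the metacognitive state, the optimal
    observer's objective criterion, and conditional meta-d' along the
    metacognitive-evidence axis, with parametric-bootstrap percentile bands.
    Also included: trial-level synthetic data generation with known ground
    truth for parameter-recovery studies, participant exclusion rules,
    confidence reclassification, per-state mean confidence with Friedman
    tests, and delimited-text/JSON import and export for every pipeline stage.
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
    mvtnorm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
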