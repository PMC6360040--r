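Package: plateletscore
Title: Composite Platelet-Reactivity Scoring and Risk-Factor Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rank-based composite scoring of blood platelet reactivity
    (van der Waerden normal scores cumulated over aggregometry agonists and
    flow-cytometry activation antigens, dichotomized at the median) together
    with the downstream inference stages used in geriatric platelet-function
    studies: resampling-validated Spearman associations, bootstrap-boosted
    ANCOVA, logistic odds-ratio models with Hosmer-Lemeshow calibration,
    Mantel-Haenszel pooled odds ratios over median-split predictors (forest
    data), stepwise discriminant ranking by partial Wilks' lambda, canonical
    correlation with redundancy indices, and a classifier panel combined by
    majority voting.  A Gaussian-copula synthetic-cohort generator reproduces
    the marginal distributions and rank-correlation structure such studies
    assume, so the whole pipeline is testable without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    Matrix,
    car,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
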