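Package: eggomics
Title: Label-Free Egg Proteome and Yolk Chemistry Analysis with Mixed
    Models and Affinity Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidy pipeline for analysing avian egg composition from
    label-free proteomics and yolk chemistry data: replicate-level
    identification and quantitation filters, total-signal normalisation,
    bounded-uniform imputation of intensity-dependent missing values,
    per-sample concentration estimation, standardised linear mixed models
    with female random intercepts and laying-order random slopes,
    affinity-propagation clustering of proteins, carotenoids and eggs,
    Monte-Carlo functional-category enrichment, and categorical association
    tests (functional chi-square, Fisher exact). Includes a synthetic-data
    generator that emulates a wild blue tit clutch-sampling design with
    known ground-truth effects, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    withr,
    ggplot2,
    generics,
    lme4,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
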