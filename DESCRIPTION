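Package: lipidrank
Title: Hierarchical Random-Forest Discovery of Discriminative Lipid Classes and Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A case-control serum lipidomics analysis pipeline: internal-standard
    normalization with optimal multiple-internal-standard selection (NOMIS),
    Monte Carlo cross-validated random-forest classification and
    variable-importance ranking, hierarchical class-to-species feature
    selection, and a statistical validation battery (Welch tests with
    Bonferroni correction, univariate and sequential multivariate logistic
    regression, ridge-based direction of effect). Includes a synthetic cohort
    generator with known ground truth so every stage is testable without
    patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
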