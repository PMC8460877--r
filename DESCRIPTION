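Package: neatlink
Title: Linking, Equating and Age Norms for Alternate Test Forms Under the 2PL Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for placing two alternate dichotomous test forms on a common
    scale under the common-item nonequivalent groups (NEAT) design. Fits the
    two-parameter logistic (2PL) item response model by marginal maximum
    likelihood, screens item pairs for local-independence violations with
    standardized bivariate Pearson residuals, reduces item pools under an
    anchor-ratio rule with content-paired selection, estimates scale linking
    coefficients by moment (mean-mean, mean-sigma) and characteristic-curve
    (Haebara, Stocking-Lord) methods, converts raw scores between forms by IRT
    true-score and observed-score (Lord-Wingersky plus equipercentile)
    equating, and builds age-specific percentile reference intervals from a
    fractional-polynomial model search. Includes a synthetic NEAT study
    generator for validation and a declarative pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
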