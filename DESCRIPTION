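Package: dietdiv
Title: Infant Diet-Diversity Scores and Food-Allergy Association Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scoring engine and association models for diet diversity of
    complementary feeding in infancy and its relation to early food allergy,
    as studied in the NorthPop birth cohort. Implements a frequency-weighted
    diet-diversity score (0-31 points) from food-frequency-questionnaire
    categories, counts of introduced foods and of introduced allergenic foods
    at 6 and 9 months, the published exposure categorisations, closed-form
    Woolf odds ratios for 2x2 tables, and DAG-informed multivariable logistic
    models with sensitivity and stratified variants. A calibrated synthetic
    cohort generator emulates the published covariate, score and missingness
    distributions so that the whole pipeline can be exercised and validated
    by parameter-recovery simulation without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
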