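Package: agecovar
Title: Distinguishing Uniform from Individualistic Rates of Ageing in
    Cross-Sectional Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to assess whether the age-related decline of a
    physiological function (muscle power, VO2max, cognitive score) in a
    study population proceeds at a 'uniform' or a 'highly individualistic'
    rate, using only cross-sectional data. Provides four generative models
    of individual decline trajectories with closed-form population moments,
    a seeded cohort simulator, age-binned dispersion curves (standard
    deviation and coefficient of variation), weighted least-squares and
    stratified-bootstrap inference on the age trend of each dispersion
    statistic, and a decision rule that maps the pair of trend directions
    to a scenario label and a coarse uniform/individualistic verdict.
    Includes a command-line interface for simulation and analysis.
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
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
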