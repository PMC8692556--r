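Package: sccosol
Title: Solubility Correlation of Solid Drugs in Supercritical Carbon Dioxide
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Correlates isothermal solid-solute solubility measurements in
    supercritical carbon dioxide with ten density-based semi-empirical models,
    a Peng-Robinson equation of state route with two-parameter van der Waals
    mixing rules, and two cluster (solvate-complex) solvation models including
    a four-parameter extended Gibbs-energy form. Provides seeded multistart
    regression against a relative-deviation objective, AICc-based model
    ranking, Mendez-Santiago-Teja self-consistency diagnostics, group
    contribution and Lee-Kesler property estimation, sublimation/solvation
    enthalpy extraction, and a synthetic-data generator. Ships the
    clemastine fumarate reference dataset as a plain-text fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    readr,
    jsonlite,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
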