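Package: delaychart
Title: Stability Charts for a Scalar Delay Characteristic Equation and a
    Quiescent Cell Population Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the transcendental characteristic equation
    lambda = alpha1 + (alpha2 + alpha3*lambda)*exp(-lambda) that arises from
    delay and renewal equations with a neutral term: exact critical-root
    boundary curves in the (alpha1, alpha2)-plane (D-partition), geometric
    stability-region membership, argument-principle root counting and root
    localisation. The package also implements the structured cell population
    model with reversible quiescence that produces this equation: the basic
    reproduction number R0(E), the unique nontrivial steady state, its
    linearisation, one-parameter (consumption weight theta) and two-parameter
    (response steepness versus theta) stability maps, and a method-of-steps
    simulator of the nonlinear system for cross-validation of the linear
    predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
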