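Package: thermnorm
Title: Thermal Reaction Norm Fitting and Bootstrap Trait Inference for
    Phytoplankton Growth Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the left-skewed unimodal growth-temperature reaction norm
    f(T) = a*exp(b*T)*(1 - ((T - z)/(w/2))^2) to replicate phytoplankton
    populations by maximum likelihood, derives the thermal traits T_opt
    (optimal growth temperature), T_max (maximum persistence temperature)
    and mu_max (highest measured growth rate), propagates parameter
    uncertainty with a residual bootstrap, and tests the effects of
    selection temperature, pCO2 and their interaction on each trait with
    per-bootstrap linear models. Includes a synthetic-data generator that
    reproduces the statistical structure of a fully factorial
    temperature-by-CO2 experimental-evolution assay, and an end-to-end
    pipeline with reproducible seeding and audit output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
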