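Package: nitroxr
Title: Nitrite Oxidation, Oxygen Consumption, and Nitrate Isotope Analysis
    for Oxygen Minimum Zones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the contribution of aerobic nitrite
    oxidation to oxygen consumption in oceanic oxygen minimum zones. Inverts
    15N-nitrite tracer endpoint measurements into nitrite and ammonia
    oxidation rates with isotope-dilution mass balance, estimates oxygen
    consumption rates from dissolved-oxygen time series with a maximal
    information coefficient linearity screen, fits Michaelis-Menten oxygen
    affinities (across-bottle and integrated within-bottle depletion fits),
    partitions oxygen consumption between nitrite oxidation and other
    processes with power-law extrapolation to the dissolved-oxygen level at
    which nitrite oxidation accounts for all consumption, and computes dual
    nitrate-isotope Delta(15,18) deviations. A forward simulator of bottle
    incubations and depth profiles provides fully synthetic, seeded test data
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
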