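Package: privetspread
Title: Spatially Explicit Forecasting of Invasive Shrub Spread and Crown Fire Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A spatially explicit, cell-based invasion forecasting pipeline for
    understorey shrub invasions of southeastern US forestlands, exercised on
    synthetic landscapes. Occupancy in each landscape cell grows logistically at
    an intrinsic rate driven by a logistic-regression habitat quality index, and
    spreads between cells through a lognormal dispersal kernel whose velocity is
    calibrated against an observed invasion pattern with Mantel's permutation
    test. Simulated occupancy feeds a zero-inflated negative binomial model of
    crown fire counts, converting projected range expansion into expected annual
    crown fire frequencies and risk categories. Includes a synthetic landscape
    generator, seeded Monte Carlo ensemble projection, and CSV-based pipeline
    drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    MASS,
    vegan,
    withr
Config/testthat/edition: 3
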