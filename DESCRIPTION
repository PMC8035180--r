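Package: c3pco2
Title: Atmospheric pCO2 Reconstruction from Carbon Isotope Fractionation in
    C3 Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs atmospheric pCO2 across a carbon isotope excursion
    (CIE) from the CO2-dependent photosynthetic carbon isotope fractionation
    of C3 land plants. Provides the hyperbolic fractionation model and its
    closed-form inversion, LOESS stacking of scattered multi-section isotope
    records onto a regular age grid, Monte Carlo propagation of proxy and
    measurement uncertainties with percentile confidence bands, CIE magnitude
    compilation statistics (Kruskal-Wallis and exact rank-sum comparisons
    across substrates), a carbon isotope mass-balance model of candidate
    carbon sources, and climate metrics (Earth system sensitivity, pCO2-SST
    correlation). A synthetic-record generator with a known true pCO2,
    d13C and sea-surface-temperature history makes the whole pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
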