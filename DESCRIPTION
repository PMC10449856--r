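Package: phenoflux
Title: Phenological Transition Dates and Their Trends from Eddy-Covariance GPP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts vegetation phenological transition dates (start of
    season, end of season, growing season length) from daily gross primary
    productivity (GPP) time series measured at eddy-covariance flux towers.
    Implements integral smoothing (smoothing the annual cumulative GPP and
    differentiating the fitted spline), direct spline and lowess smoothing,
    multi-threshold and first-derivative phenometrics with cross-year and
    multi-season handling, Theil-Sen/Mann-Kendall trend estimation with a
    threshold-uncertainty classification, and weekly GPP trend analysis
    coupling phenology shifts to carbon-uptake changes. Includes a synthetic
    flux-series generator with analytic ground-truth transition dates, and
    readers/writers for the FLUXNET FULLSET daily CSV dialect with the usual
    data-quality filters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
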