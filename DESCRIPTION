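Package: limnotrace
Title: Trace-Element Flux Histories from Lead-210 Dated Lake-Sediment Cores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs pollution histories from short lake-sediment cores.
    Builds constant-rate-of-supply (CRS) lead-210 chronologies with a
    missing-inventory correction and linear age extrapolation below the dated
    range, derives mass accumulation rates, converts element concentrations to
    fluxes, apportions total fluxes into background, erosion-driven and
    atmospheric/point-source fractions, and assesses contamination against
    sediment-quality thresholds (LEL, ERL, agricultural-soil values). Includes
    a synthetic two-lake core simulator with known ground truth for validating
    every pipeline stage, and QA/QC helpers (recovery correction, limits of
    detection, replicate relative standard deviations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
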