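Package: nremspec
Title: Composite Parametrization of NREM Sleep EEG Power Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces non-rapid-eye-movement (NREM) sleep EEG power spectra to a
    small set of non-redundant parameters: the power-law (colored-noise)
    background slope and intercept fitted on an equidistant log-log grid with
    oscillatory bands excluded, slope-free alternative intercepts, and the
    frequency and whitened amplitude of the maximal spectral peak in the sleep
    spindle (9-18 Hz) range.  Includes Welch-style averaged periodograms from
    staged, artifact-masked polysomnography, device calibration correction,
    antero-posterior spindle topography, cohort-level statistics with
    Rueger-area multiple-testing control, and synthetic-data generators
    (spectra, time series, cohorts) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    pracma,
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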