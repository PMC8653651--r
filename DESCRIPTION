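Package: ftirquant
Title: Quantifying Botanical Powder Adulteration from ATR-FTIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometric workflow for quantifying the weight fraction of an
    adulterant botanical powder mixed into a target botanical powder from
    mid-infrared (ATR-FTIR) absorbance spectra. Provides a synthetic spectra
    generator for two-component mixture designs, spectral pretreatment chains
    (standard normal variate, multiplicative scatter correction and
    Savitzky-Golay derivatives), PLS1 regression with leave-one-out and k-fold
    cross-validation, three wavelength-selection algorithms (moving-window PLS,
    Monte-Carlo uninformative variable elimination and interval random frog),
    and an end-to-end study pipeline with tabular reports, reading and writing
    wide tabular and JCAMP-DX spectra files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
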