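Package: waveratio
Title: Wavelet De-Noising and Stable-Isotope Ratio Quantification for LC-MS
    Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies relative peptide and protein abundance from
    stable-isotope-labelled (ICAT/SILAC-style) LC-MS experiments. Extracted-ion
    chromatograms of light and heavy peptide partners are de-noised with an
    orthonormal discrete wavelet transform, a Donoho-Johnstone universal
    threshold with a hybrid hard/soft shrinkage rule, and a spatially adaptive
    cross-scale correlation algorithm that protects genuine chromatographic
    peaks while suppressing noise. De-noised peak areas yield light/heavy
    ratios per charge state, which are merged into peptide ratios and
    aggregated into protein ratios by recursive square-root-range outlier
    elimination. A synthetic-data generator with analytic ground truth and a
    minimal mzML reader/writer make the whole pipeline testable end to end.
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
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
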