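Package: sersmix
Title: Mixture Recognition for Surface-Enhanced Raman Spectra Trained on
    Pure-Compound Spectra Only
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Recognises binary and ternary mixture categories in
    surface-enhanced Raman spectroscopy (SERS) spectra using a model trained
    exclusively on pure-compound spectra. Provides a synthetic SERS spectrum
    generator with non-linear peak masking, the standard Raman preprocessing
    chain (fingerprint-region resampling, Savitzky-Golay smoothing, iterative
    polynomial baseline correction, min-max plus power-law normalisation), a
    one-dimensional residual convolutional encoder with a large-margin cosine
    classification branch and a sigmoid component-evidence branch, AdamW
    training with mixture-aware checkpoint selection, and a two-stage
    inference procedure combining set-likelihood ranking with nonnegative
    least-squares residual refinement. Includes confusion-matrix metrics and
    one-dimensional Grad-CAM attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
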