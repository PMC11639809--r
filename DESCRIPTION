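Package: ovirr
Title: Non-Contact Respiratory Rate Estimation for Sheep from RGB and NIR Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Estimates the respiratory rate of resting sheep from visible
    (RGB) or near-infrared (NIR) video without contact. The segmented thorax
    is tracked with FAST feature points and pyramidal Lucas-Kanade optical
    flow; trajectory derivatives are band-pass filtered to the ovine
    breathing band (0.33-0.67 Hz), separated with principal component
    analysis, and the respiratory rate is extracted as the dominant in-band
    frequency of a sliding spectral window. Includes a synthetic
    breathing-video generator with known ground truth, regional thorax
    analysis, and agreement statistics (mean absolute and relative error,
    Pearson correlation, Bland-Altman limits, rest coverage).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    Rcpp,
    signal,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
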