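Package: fdlquant
Title: Dual-Channel Immunofluorescence Densitometry and Chromogenic
    Intensity Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for two-channel (red/green)
    immunofluorescence microscopy and semiquantitative chromogenic
    immunohistochemistry. Segments neuron-scale objects from merged
    two-channel images (Otsu or fixed thresholding, connected components
    with a strict pixel-area filter), redirects measurement of raw
    integrated density to the original channel rasters, expresses each
    object's red and green signals as proportions of their sum, and maps
    them to the normalized difference index X = (R - G)/(R + G) on
    [-1, +1]. Includes a synthetic virtual-slide generator with ground
    truth for benchmarking, per-neuron 0-3+ chromogenic scoring with
    case and group aggregation, and the accompanying statistical plan
    (Shapiro-Wilk normality gate, pairwise equal-variance t-tests,
    ANCOVA with clinical covariates, tie-aware Spearman correlation with
    exact small-sample p-values).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    jsonlite,
    yaml,
    car,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
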