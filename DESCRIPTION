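Package: bbbleak
Title: Automated Quantitation of Blood-Brain Barrier Leakage from
    Immunofluorescence Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Machine-learning quantitation of blood-brain barrier (BBB)
    permeability from two-channel immunofluorescence micrographs. A pixel
    classifier trained on sparse brush annotations segments laminin-alpha-4
    stained microvessels; the extravascular (parenchymal) compartment is
    derived by morphological erosion of the non-vessel class; extravasated
    immunoglobulin G (IgG) is then quantified by intensity thresholding
    within that compartment, with region-area filtering and per-image
    tabulation. Includes an ilastik-style filter-bank feature stack, exact
    Potts-model spatial regularization by graph cut, a synthetic micrograph
    simulator with ground truth for validation, batch analysis, and a
    coefficient-of-variation reproducibility statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    generics,
    ggplot2,
    randomForest,
    Rcpp,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    dplyr,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
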