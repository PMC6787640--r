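Package: aosediment
Title: Semi-Automated Urine Sediment Analysis from Acridine Orange
    Fluorescence Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments acridine-orange-stained urine sediment objects in
    color fluorescence micrographs, extracts red-to-green-ratio and
    calibrated-area features, classifies objects as epithelial cells,
    leukocytes, bacteria or out-of-focus cellular debris by area-threshold
    rules, and reports per-specimen counts in the clinical range
    vocabulary (Trace/Few/Moderate/Many). Includes a seeded synthetic
    phantom generator with full ground truth so every pipeline stage is
    testable without patient images, and a pairwise multi-rater percent
    agreement statistic for manual classification tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
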