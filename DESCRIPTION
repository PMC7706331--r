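Package: grapecolor
Title: Image-Based Phenotyping and QTL Mapping of Grape Berry Color
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying grape cluster color from
    RGB photographs and mapping the loci that control it. Images are color
    corrected against a reference card, segmented into berry, rachis and
    background classes with a nearest-prototype classifier trained from
    user-picked 3x3 pixel patches, and summarized as eleven color traits
    (RGB, HSI, CIELAB, weighted and average greyscale). Downstream tools
    cover OIV score binarization, 1:1 segregation tests, normality screens,
    between-year correlations, PCA, and pseudo-testcross QTL scans (simple
    interval mapping by Haley-Knott regression, a rank-based nonparametric
    scan, and a binary logistic scan) with permutation significance
    thresholds, 1.5-LOD support intervals and percent variance explained.
    Synthetic cluster-image and cross simulators provide ground truth for
    validating every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
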