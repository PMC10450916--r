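Package: echotex
Title: Gray-Level Co-Occurrence Texture Analysis for Ultrasound Images
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative texture analysis for B-mode ultrasound images:
    gray-level co-occurrence matrix (GLCM) construction with configurable
    distance, angle and gray-level count; seven Haralick-style texture
    features (entropy, angular second moment, energy, contrast,
    dissimilarity, homogeneity, correlation); batch feature extraction over
    rectangular regions of interest with lossless CSV import/export;
    principal component exploration of feature tables with labeled biplots
    and feature-correlation reporting; and a seeded synthetic
    ultrasound-phantom generator (Rayleigh speckle, hyperechoic microlith
    foci, septated cystic lesions, heterogeneous parenchyma) so that every
    stage of the pipeline can be validated end to end without clinical
    images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    ggplot2,
    grid,
    jsonlite,
    png,
    readr,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
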