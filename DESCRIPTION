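Package: fibroquant
Title: Layer-Resolved Digital Quantification of Cardiac Fibrosis and
    Adipose Tissue on Trichrome-Stained Heart Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies connective tissue (fibrosis), cardiomyocytes and
    adipose tissue on Masson's trichrome stained transverse heart-slice
    images. Separates the stain into methyl-blue and ponceau-fuchsin
    concentration maps by colour deconvolution, classifies tissue with
    median filtering and binary morphology including a dedicated
    "chain-link" adipocyte detector, partitions each section into
    epicardial, outer/inner compact and trabecular myocardial layers via
    an equidistant midline built from Euclidean distance transforms, maps
    per-section percentages onto a standardized per-degree circular
    schematic with an eight-region anatomical grouping, and analyses the
    resulting repeated-measures tables with a split-plot ANOVA under
    Greenhouse-Geisser correction and Tukey HSD post-hoc tests. Includes
    a synthetic phantom generator producing trichrome-like images,
    annular slice geometries and repeated-measures datasets with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
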