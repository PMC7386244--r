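Package: spotstack
Title: Image Processing, Serial-Section Alignment and Spatial Statistics for
    Spot-Based Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for spot-based spatial transcriptomics (10x Genomics
    Visium and legacy ST arrays): reading Space Ranger-style output, tissue
    masking of H&E images (Otsu thresholding, SLIC superpixels, k-means),
    automatic serial-section alignment by iterative closest point on tissue
    edges, hexagonal spot neighbor graphs with spatial-lag autocorrelation
    gene ranking, region-neighbor extraction and Wilcoxon differential
    expression, non-negative matrix factorization with ICA initialization on
    non-negative Pearson residuals, HSV multi-feature spot rendering, and 3D
    nuclei point-cloud assembly across aligned sections. Includes a seeded
    synthetic-data generator producing H&E-like section images, hexagonal
    lattices and spatially patterned negative-binomial counts for fully
    offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    EBImage,
    ica,
    jsonlite,
    png,
    generics,
    methods,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
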