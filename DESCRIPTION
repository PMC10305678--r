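Package: codfusion
Title: Absorption-Fluorescence Spectral Fusion for Water COD Retrieval
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrieves chemical oxygen demand (COD) of water samples by fusing
    UV-Vis absorption spectra with excitation-emission matrix (EEM)
    fluorescence. Provides COD conversion-coefficient chemistry and mixture
    labeling, a synthetic spectra generator (Beer-Lambert additive absorption,
    Gaussian fluorophores, inner-filter distortion, Rayleigh/Raman scatter),
    EEM preprocessing (Delaunay-interpolation scatter removal, cubic-spline
    upsampling, label-interpolation augmentation), a 2D Gabor filter-bank
    texture feature extractor, coefficient-of-variation guided dimensionality
    reduction (PCA, FastICA, Isomap, LLE, random projections), and a
    dual-branch 1D convolutional fusion network trained with Adam that
    regresses COD from the fused feature matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
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
    tools,
    utils,
    vegan,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
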