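Package: stisebs
Title: Superpixel Segmentation of Dense Spatial Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised superpixel segmentation for gridded vegetation-index
    time series (STiSeBS: Spatial Time Series-Based Superpixels). Reduces the
    spatial dimensionality of dense NDVI grids with minimal information loss by
    chaining principal-component reduction of per-pixel series, seeded k-means
    clustering, connected-component patch dissolution, and SKATER
    minimum-spanning-tree regionalization. Includes NDVI preprocessing
    (range filtering, exponential gap filling, Savitzky-Golay smoothing),
    segmentation quality assessment (time-series deviation, inhomogeneity and
    isolation, land-cover confusion metrics with kappa and Matthews
    correlation), coarse-pixel and SLIC-on-components baselines, a seeded
    synthetic scene generator, and a minimal GeoTIFF reader/writer for stacks
    and label rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal,
    e1071,
    withr
Config/testthat/edition: 3
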