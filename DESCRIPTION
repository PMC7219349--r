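Package: fsflicm
Title: Robust Local Fuzzy Clustering for Noisy Image Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Unsupervised segmentation of single- and multi-channel raster
    images by fuzzy c-means clustering with local spatial information.
    Implements fuzzy c-means (FCM), the fuzzy local information c-means
    baseline (FLICM), a membership-constrained improvement of FLICM, and a
    feature-selection Gaussian-mixture local fuzzy clustering algorithm with
    Kullback-Leibler regularization and median-filtered membership
    postprocessing, designed for images corrupted by Gaussian,
    salt-and-pepper, multiplicative (speckle), or mixed noise.  Includes
    piecewise-constant phantom generators with the matching noise models,
    misclassification-rate scoring with optimal label matching, PSNR
    evaluation against class-mean reconstructions, and a command-line
    interface for reproducible segmentation benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    tiff,
    jsonlite,
    optparse,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
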