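Package: histocascade
Title: Cascaded Multi-Class Classification of H&E Tissue Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cascaded multi-class classification of stained tissue
    regions of interest. Implements Ruifrok-style color deconvolution of H&E
    images into stain-density channels, nuclear centroid detection by Otsu
    thresholding, Euclidean distance transform and marker-based watershed,
    nuclear-architecture features from Voronoi, Delaunay, minimum-spanning-tree
    and density statistics, a 540-feature texture bank (first-order,
    co-occurrence and Gabor filter statistics on hue/saturation/intensity
    channels), three multi-class strategies (cascaded, one-shot,
    one-versus-all) over entropy decision trees with per-class
    accuracy/PPV/NPV, and AdaBoost decision-stump feature ranking. Ships a
    synthetic H&E-like tissue generator with known ground truth so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    deldir,
    grDevices,
    igraph,
    jsonlite,
    png,
    rpart,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
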