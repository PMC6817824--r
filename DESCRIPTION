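Package: slimeTrace
Title: Quantifying Slime Mold Exploration from Time-Lapse Images
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated analysis of time-lapse photographs of Physarum
    polycephalum exploring a circular petri-dish arena. Frames are converted
    to the ab* chromatic plane, binarized into slime / not-slime by
    two-cluster k-means, and refined by pixel history into a three-class
    labeling (slime, mucus, unexplored substrate). Per-interval growth events
    (primary growth, secondary growth, refinement) are classified and
    accumulated; migration rate, expansion region and the bias toward
    regrowth over mucus are quantified; per-frame shape indices (circularity,
    eccentricity, solidity, erosion-based pseudopod count) and distance to an
    attractant spot with an empirical time-to-contact survival curve are
    computed. A synthetic time-lapse generator with known ground truth makes
    the whole pipeline testable without original photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    igraph,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    optparse,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: CellBiology, Segmentation, TimeCourse, Visualization
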