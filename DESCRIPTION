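Package: airtree
Title: Airway Tree Segmentation, Centerline Extraction and Evaluation for Thoracic CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for segmenting the bronchial tree from thoracic CT volumes and
    extracting its centerline. Implements a multi-scale Hessian tube-detection
    filter with automatic lung-region cropping, topology-preserving 3D thinning
    for centerline extraction, seeded region growing with a gradient-calibrated
    leakage gate, and threshold-interval region growing as a comparator.
    Includes airway-tree metrics (branch counts per generation, total centerline
    length, segmented volume), EXACT09-style reference evaluation (branch
    detection, tree-length detection, false-positive rate, leakage count and
    volume with trachea and main-bronchus exclusions), a synthetic
    branching-airway phantom generator with exact ground truth, and readers and
    writers for MetaImage volumes and VTK legacy polydata centerlines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
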