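Package: pamvasc
Title: Vascular Morphometry and Plaque Quantification for Photoacoustic
    and Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("pamvasc", "developers", email = "pamvasc@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of maximum-amplitude-projection
    photoacoustic microscopy (PAM) angiograms and confocal fluorescence
    microscopy (CFM) images of the rodent cerebral cortex.  Implements
    histogram equalization, single-scale Frangi (Hessian) vesselness
    filtering, three-way vessel binarization with the combination rule
    (MAP1 AND MAP3) OR MAP2, topology-preserving skeletonization,
    segment-level diameter morphometry, size-binned vessel length
    density (VLD), edge-spread-function resolution characterization,
    amyloid plaque counting, and pooled two-sample group statistics.
    Ships a synthetic phantom generator (branching vascular trees,
    Gaussian point-spread blur, hemorrhage blobs, punctate plaque
    fields) with exact ground truth, so every stage of the pipeline is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
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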