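Package: lungparc
Title: Bronchopulmonary Segment Parcellation from Airway Centerline Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for CT-based parcellation of the lungs into the 18
    bronchopulmonary segments. Provides the three-level lung anatomy
    (lungs, lobes, segments) as queryable constants; rooted airway
    centerline trees with branch decomposition, generation levels,
    tertiary-bronchus identification, label propagation and SWC input
    and output; centerline probability maps built from a Euclidean
    distance transform with Gaussian weighting; a geodesic fast-marching
    tracer with iterative backtracking that extracts centerline trees
    from probability maps and bridges small gaps; lobe-constrained
    nearest-bronchus segment parcellation with lobe-based
    regularization and landmark-driven crop or resample; segmentation
    metrics (Dice, 95th-percentile Hausdorff distance, average
    symmetric surface distance, bronchial inclusion rate); and a
    synthetic thoracic phantom generator so the whole pipeline is
    testable without patient data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
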