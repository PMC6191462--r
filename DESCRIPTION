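Package: qvtools
Title: Quantitative Vessel Tortuosity of Nodule-Associated Vasculature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the tortuosity of vasculature associated with lung
    nodules on CT. Segments nodule-associated vessels from Hounsfield-unit
    volumes by seeded region growing, extracts sub-voxel centerlines with a
    fast-marching backtracking scheme, and computes a 35-element descriptor of
    torsion (chord-to-arc ratio), Menger curvature, branching and volume
    statistics. Includes minimum-redundancy maximum-relevance (mRMR) feature
    selection, test-retest stability via the intraclass correlation
    coefficient, cross-validated SVM/KNN/naive-Bayes classification with ROC
    analysis, co-occurrence consensus clustering, and a synthetic vascular
    phantom generator with analytic ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    e1071,
    class,
    cluster,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
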