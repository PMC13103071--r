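Package: maskqc
Title: Unsupervised Quality Control of Brain Extraction Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Training-free quality control for 3D binary brain masks
    produced by skull-stripping algorithms. Morphological shape features
    are extracted from each mask, a baseline model is fitted to a
    ground-truth cohort by k-means clustering with Rand-index stability
    selection of the cluster count, and candidate masks are scored by
    cluster-conditional Mahalanobis distances combined into an
    arctan-squashed similarity score r; masks with r above a cutoff are
    flagged as faulty. Includes a Dice / 95th-percentile Hausdorff
    evaluation harness and a deterministic synthetic mask generator so
    the whole pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
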