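Package: mapeval
Title: Retrieval-Based Evaluation of High-Dimensional Perturbation Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Evaluates high-dimensional perturbation profiles (image-based
    morphological, proteomic, or transcriptomic) as an information-retrieval
    problem. Replicate profiles of a perturbation are ranked against reference
    (control) profiles by a distance metric, non-interpolated average precision
    is computed per query, and group-level mean average precision (mAP) is
    assigned a permutation p-value from the exact or Monte-Carlo null of the
    binary rank list. Supports metadata-driven block designs (same/different
    column constraints), phenotypic activity, consistency and distinctiveness
    assessments, a multi-label extension, three comparator multivariate
    two-sample methods (PCA/Mahalanobis mp-value, maximum mean discrepancy,
    k-means separation), and a simulation benchmark of recall and type-I error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    arrow,
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
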