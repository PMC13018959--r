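Package: fuzzrad
Title: Fuzzy-Mask Radiomics with Membership-Weighted Feature Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Radiomic feature extraction from CT volumes using fuzzy
    (real-valued membership) tumor masks. Generates fuzzy masks from binary
    delineations by Gaussian fuzzification together with their alpha-cut core
    and support companions, extracts membership-weighted intensity,
    intensity-histogram, grey-level co-occurrence (GLCM) and neighbouring
    grey-level dependence (NGLDM) features, quantifies feature and model
    reliability under a simulated delineation-uncertainty perturbation chain
    via the consistency intraclass correlation ICC(C,1), measures feature
    redundancy by hierarchical clustering at a correlation-distance threshold,
    and evaluates penalized Cox survival models over repeated train/validation
    splits. Includes a synthetic CT phantom and cohort generator so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    glmnet,
    survival,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
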