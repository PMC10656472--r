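Package: tbiquant
Title: Regional Quantification of Traumatic Brain Lesions and Prediction of Therapeutic Intensity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies traumatic brain injury (TBI) lesion volumes by lesion type and
    atlas region from multiclass label volumes (NIfTI), computes clinical severity scores
    (daily therapeutic intensity level TILsum, Marshall and Rotterdam CT scores), evaluates
    automatic segmentations against references with Dice overlap, and predicts extreme
    therapeutic intensity (TILsum >= 11 within the first eight ICU days) with a nested
    cross-validated tree-ensemble classifier, including Mean Decrease Impurity importances,
    Mann-Whitney comparisons and BCa bootstrap confidence intervals. Ships a synthetic-data
    generator (atlas, lesions, segmentation degrader, coupled clinical cohorts) so the whole
    pipeline is exercisable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    boot,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
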