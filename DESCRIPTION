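Package: centiloidr
Title: MRI-Free Amyloid-PET Centiloid Quantification and Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Parcellation-driven SUVR extraction from amyloid PET volumes
    (whole-cerebellum, cerebellar-gray, pons and eroded-white-matter
    composite reference regions), chained linear Centiloid calibration with
    Level-1 acceptance checking, and the cohort-level validation statistics
    used to compare quantification pipelines: pooled-SD effect sizes with
    bootstrap confidence intervals, variance-homogeneity tests with
    Bonferroni correction, and ROC analysis with a Youden-optimal cutoff.
    Ships a synthetic phantom and cohort generator so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    car,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
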