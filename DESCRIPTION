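Package: octaquant
Title: Quantification of Retinal Microvasculature from OCTA En Face Angiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing and cohort analysis for optical coherence
    tomography angiography (OCTA) en face images of the retinal capillary
    plexuses. Provides Hessian-based vessel enhancement, adaptive
    binarization, skeleton-based vessel density, large-vessel perfusion
    density, box-counting fractal dimension, and foveal avascular zone
    (FAZ) geometry within a fovea-centered annulus; covariate-adjusted
    group comparisons with estimated marginal means, paired ROC/AUC
    testing, and post hoc power calculations; plus a synthetic angiogram
    and cohort generator with exhaustive ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    emmeans,
    optparse,
    withr
Config/testthat/edition: 3
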