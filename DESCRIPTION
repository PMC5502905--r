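Package: plaquet2
Title: Carotid Plaque T2 Mapping, Lipid-Core Segmentation and Validation
    Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise T2 relaxometry for multi-echo spin-echo carotid
    imaging, dual-threshold segmentation of the lipid-rich necrotic core
    (including recent intraplaque haemorrhage), exhaustive threshold
    calibration against histology with leave-one-out cross-validation, and
    the accompanying agreement and group-discrimination statistics
    (Bland-Altman, ROC, intraclass correlation, within-subject coefficient
    of variation, Cohen's kappa, modified AHA plaque typing). A seeded
    synthetic phantom and cohort generator emulates the imaging and
    histology ground truth so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    pROC,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
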