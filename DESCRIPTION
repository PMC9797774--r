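Package: strokescore
Title: Evaluation Toolkit for Two-Stage Stroke CT Segmentation Challenges
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring and data-handling machinery for two-stage stroke
    computed-tomography competitions: a boundary-tolerant multi-class
    intersection-over-union metric in which predictions are compared against
    morphologically eroded and dilated envelopes of the radiologist ground
    truth, an F1-based qualification gate for image-level stroke detection,
    rank-to-points leaderboard aggregation, readers and writers for the
    four-folder dataset layout (DICOM, display PNG, label-mask PNG, overlay
    PNG), a whitelist-based DICOM anonymizer, a registry cohort filter driven
    by ICD-10 and procedure codes with a time window, and seeded synthetic
    generators for lesion phantoms, degraded team submissions, DICOM files
    and case registries so the whole pipeline can be exercised without the
    original clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    withr,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
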