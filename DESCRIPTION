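Package: ctvqa
Title: Quality Assurance Metrics for Auto-Delineated Radiotherapy Target Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validation pipeline for atlas-based auto-segmentation of rectal
    clinical target volumes (CTVs) against expert reference contours. Implements
    contour-overlap metrics (volumetric Dice similarity coefficient, slicewise
    symmetric Hausdorff distance and its cohort mean, MSHD), delineation-time
    analysis with paired statistics, a multi-criterion acceptance decision
    engine with a mandatory time-saving criterion, Gower-style atlas-patient
    ranking, and a seeded synthetic cohort generator emulating expert and
    auto-segmented contour sets with correlated boundary perturbation and
    lognormal timing models. Contours are exchanged as stacks of closed planar
    polygons in millimetre coordinates (JSON), with optional DICOM RT-STRUCT
    ingest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
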