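Package: cortexcad
Title: Cortical Surface Shape Analysis and Region-Based Diagnosis of Mild
    Cognitive Impairment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A personalized computer-aided diagnosis pipeline for mild
    cognitive impairment (MCI) from preprocessed structural MRI. Reconstructs
    the cerebral cortex from a labeled volume by isosurface extraction,
    estimates per-vertex principal curvatures by local quadric fitting,
    aggregates curvature descriptors and enclosed volume per AAL cortical
    region, fuses the five regional features by sequential canonical
    correlation analysis, and performs a two-layer diagnosis: one calibrated
    probabilistic classifier per cortical region followed by a global NC/MCI
    decision. Includes voxelized geometric phantoms with analytic curvature
    and volume, and a two-group synthetic cohort generator with planted
    regional effects, so every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    class,
    optparse,
    randomForest,
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
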