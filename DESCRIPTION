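Package: spineclass
Title: Radiation-Free Classification of Adolescent Idiopathic Scoliosis from
    3D Vertebral Centroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies adolescent idiopathic scoliosis (AIS) from ordered 3D
    vertebral and intervertebral-disc centroids without radiographs. A
    centroid sequence is normalized to a canonical frame (L5 at the origin,
    the L5-C7 chord vertical at 500 mm), densely interpolated with a cubic
    spline at 1 mm arc spacing, and projected onto the frontal and sagittal
    planes. Quadrant dispersion values (thoracic/lumbar x left/right RMS
    lateral displacement) yield continuous severity, sidedness (s), vertical
    (v) and kyphosis-lordosis (kl) indices that are mapped through
    configurable thresholds to categorical labels and a natural-language
    description, with apex identification and a color-coded geometric report.
    Includes a synthetic spine cohort generator for validation, and a
    concordance module (contingency tables, Pearson chi-square, percent
    agreement, charts) for comparing descriptions against the Lenke
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
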