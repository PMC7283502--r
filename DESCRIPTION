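Package: strawdetect
Title: Strawberry Detection and Plumpness Grading from Greenhouse RGB Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for detecting strawberries in greenhouse
    RGB images and grading their plumpness from bounding-box geometry. It
    provides a seeded synthetic-scene generator with exact ground truth,
    Pascal-VOC-style XML annotation input/output, the photometric
    augmentation and patching pipeline used for small fruit datasets, a
    trainable region-proposal detector built on residual convolutional
    blocks with a hybrid leaky-ReLU/softplus head activation, curvature-
    guided watershed post-processing that splits adhered fruit regions and
    recovers occluded ones, aspect-ratio plumpness grading into three
    bands, and detection evaluation indices (accuracy, intersection-over-
    union, F-measure, average running time, count correlation) together
    with robustness-experiment harnesses over dataset size and
    illumination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    xml2,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
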