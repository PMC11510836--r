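Package: fuzzycontrast
Title: Fuzzy Local-Contrast Enhancement for Grayscale Medical Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a twelve-step fuzzy-logic contrast enhancement
    pipeline for 8-bit grayscale images such as chest radiographs:
    min-max normalization, Cauchy-type fuzzification with intensification
    (INT) refinement, sliding-window local features (local and global
    contrast, histogram spread, fuzzy entropy, fuzzy standard deviation),
    feature-driven selection of a per-pixel enhancement exponent, a
    nonlinear local-contrast transform, and mean-anchored reconstruction.
    Includes a dataset builder that triples a class-labeled image folder
    into three enhanced variants with a leakage-safe stratified
    train/test/validation split, shape calculus and constructors for a
    single-branch CNN and a three-branch concatenated CNN classifier,
    binary classification metrics, and a seeded generator of synthetic
    chest-X-ray-like fixtures for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    EBImage
Config/testthat/edition: 3
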