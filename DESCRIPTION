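Package: stackops
Title: Operator-Based Image and Signal Stack Processing with Local
    Binary Patterns and Time-Lapse Phase Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A scriptable toolkit for batch ("stack") processing of
    heterogeneous images and one-dimensional signals through a registry of
    validated operators.  Operators declare their identity, source arity
    and parameter ranges in a descriptor, are checked by per-operator
    validators, and return multi-dimensional results (images, signals and
    tables).  Stacks may be processed serially or in parallel, in memory
    or in a disk-backed "virtual" mode.  Built-in operators include
    histogram normalization, absolute difference images,
    histogram-statistics (energy, entropy, skewness, kurtosis), Gaussian
    smoothing, difference-of-Gaussians edge extraction, seeded region
    growing, and a rotation-invariant Local Binary Pattern texture
    descriptor with circular bilinear sampling and cell-wise histograms.
    On top of these, the package provides a deterministic pipeline that
    recovers proliferation-phase boundaries and the monolayer-formation
    frame from phase-contrast time-lapse microscopy of cultured cells, and
    a synthetic time-lapse generator with ground-truth labels for
    validating the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    jsonlite,
    parallel,
    stats,
    tools,
    utils
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
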