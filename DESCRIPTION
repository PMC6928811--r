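Package: wbcquant
Title: Integer-Only Quantized CNN Inference for Lensless White Blood Cell
    Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A bit-accurate, integer-only inference engine for small
    convolutional neural networks that classify white blood cells
    (lymphocytes, monocytes, neutrophils) in low-resolution lensless
    microscopy images. Implements a hardware-oriented post-training
    quantization algebra with per-kernel weight scales, unification of
    per-kernel convolution results, offset-eliminating bias and
    batch-normalization constants, and fixed-point requantization by
    integer multiply and arithmetic shift. Ships a float reference
    network and trainer, min/max calibration, a seeded synthetic
    generator of lensless-style cell images with ground-truth masks, a
    quantization bit-width degradation sweep, and a timing model of a
    dual configuration register group accelerator pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png,
    yaml,
    EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'quant-core.R'
    'float-net.R'
    'int-inference.R'
    'oracle.R'
    'calibration.R'
    'wbc-metrics.R'
    'synthetic-cells.R'
    'pipeline-sim.R'
    'io.R'
    'cli.R'
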