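Package: grainscan
Title: Morphometric Descriptors and Neural Quality Classification of Cereal Grain Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis pipeline for quality classification of malting
    barley grain. Segments individual kernels from bench images, computes a
    64-descriptor feature bank (geometric parameters, classical shape
    coefficients, RGB/HSV colour statistics, and grey-level co-occurrence,
    run-length and gradient texture features), reduces the descriptor space by
    principal component analysis, and classifies grains as good or damaged
    with a single-hidden-layer perceptron trained by back-propagation with
    momentum and refined by conjugate gradients. Includes a synthetic grain
    image generator with controllable damage modes (mold darkening, halves,
    dehulling, darkened ends) so the whole pipeline can be exercised and
    validated with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
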