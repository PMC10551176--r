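Package: endosmoke
Title: Surgical Smoke Frame Classification with a Re-Parameterized
    Convolutional Poolformer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects electro-cautery smoke in endoscopic video frames so that
    downstream desmoking can be applied selectively. Implements a
    MetaFormer-style classifier whose token mixer is a multi-branch depthwise
    convolutional block (ConvNeXt-like large-kernel plus small-kernel plus
    identity branches) that is structurally re-parameterized into a single
    depthwise convolution for inference, together with a convolutional
    tokenizer, sequence-pooling classification head, a procedural generator of
    labeled synthetic smoke/smoke-free endoscopic-style images, and a
    training/evaluation pipeline with stratified cross-validation and
    accuracy/sensitivity reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    png,
    yaml,
    jsonlite,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
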