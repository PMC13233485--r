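Package: cssnn
Title: Compressed-Sensing Spiking Neural Networks with a Neuromorphic
    Dataflow Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building and training compressed-sensing spiking
    neural networks (CSSNNs): a learnable binary {0,1} measurement-matrix
    encoder co-optimized with a leaky integrate-and-fire (LIF) classifier
    via surrogate-gradient spatio-temporal backpropagation. Includes
    post-training fixed-point quantization of weights and membrane
    potentials, a behavioral simulator of an index-matching neuromorphic
    processor dataflow with exact read/write/cycle counters, closed-form
    operation-count and model-size cost models, synthetic sparse-frame and
    event-frame dataset generators, and an IDX (MNIST-style) reader.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
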