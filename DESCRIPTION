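Package: mccnn
Title: Multichannel Convolutional Neural Networks for Biomedical Relation Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for extracting binary relations such as
    drug-drug interactions (DDI) and protein-protein interactions (PPI) from
    annotated biomedical sentences. Reads DDIExtraction-2013-style and unified
    PPI learning-format XML corpora, enumerates candidate entity pairs, blinds
    target entities (Entity1/Entity2/EntityOther), filters same-name and
    coordinate-structure noise pairs, stacks several pretrained word-embedding
    tables into a multichannel input tensor, and classifies each pair with a
    convolutional neural network (multi-width filters, max-over-time pooling,
    softmax) trained by minibatch negative log-likelihood with Adadelta,
    Gaussian input noise and a max-norm constraint on the softmax weights.
    Includes micro-averaged evaluation over positive classes, binary
    interaction-detection scoring, cross-validation splitting, and a synthetic
    corpus generator for controlled experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
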