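Package: ddicnn
Title: Convolutional Neural Networks for Drug-Drug Interaction Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies candidate drug pairs in biomedical sentences into the
    five DDIExtraction-2013 relation classes (advice, effect, int, mechanism,
    other) with a single-hidden-layer convolutional neural network over word
    and relative-position embeddings. Provides a reader and writer for the
    unified PPI/DDI annotated-corpus XML dialect, the full preprocessing
    pipeline (entity blinding, tokenization, padding), word2vec vector
    loading, a reproducible training and hyper-parameter sweep harness,
    shared-task style micro-averaged scoring with chi-square model
    comparison, and a synthetic annotated-corpus generator so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
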