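Package: lextriple
Title: Lexicon-Fused Cascading Pointer Networks for Overlapping Triple
    Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Joint entity-relation extraction from character-level text
    (agricultural variety reports and similar attribute-dense prose) with a
    lexicon-enhanced encoder and a cascading binary pointer network. A small
    Transformer encoder stack injects attention-weighted word vectors from a
    domain lexicon into the character stream at a configurable depth, a
    bidirectional LSTM adds forward/backward context, and start/end sigmoid
    pointer taggers first locate head-entity spans and then, conditioned on
    each head, tag tail spans per relation so that one head can yield many
    overlapping triples. Includes word2vec-text lexicon I/O, pointer ("01")
    label conversion, JSONL corpus I/O, a synthetic variety-report corpus
    generator, trainers with exact-match precision/recall/F1 evaluation, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
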