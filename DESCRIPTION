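Package: chemner
Title: Chemical Named-Entity Recognition with Tag Schemes, Fine-Grained
    Tokenization and Linear-Chain CRFs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for recognizing mentions of chemical compounds and
    drugs in abstracts. Provides offset-preserving sentence splitting with
    coarse (Penn-Treebank-style) and fine-grained tokenization, four entity
    tag schemes (IOB, IOBE, IOBES, IOB12E) with robust decoding of
    ill-formed model output, a battery of word, affix, orthographic,
    word-shape and syntax features, a linear-chain conditional random field
    trained by regularized maximum conditional likelihood with
    forward-backward marginals and entity-level confidence, micro and macro
    entity-level evaluation for the document-indexing (CDI) and
    mention-recognition (CEM) tasks, a resampled paired significance test
    for comparing configurations, and a seedable generator of synthetic
    annotated corpora so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
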