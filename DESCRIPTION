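Package: chemner
Title: Chemical Named Entity Recognition with Linear-Chain CRF and Structured SVM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for recognizing chemical entity mentions in biomedical
    abstracts. Provides rule-based sentence splitting and tokenization with
    exact character-offset bookkeeping, BIO sequence encoding, a feature
    extractor covering bag-of-word, orthographic, morphological,
    part-of-speech, document-structure, domain-lexicon and unsupervised
    word-representation features (Brown clustering, random indexing and
    skip-gram embeddings with k-means discretization), linear-chain sequence
    labelers trained either as a conditional random field by regularized
    maximum likelihood or as a structured support vector machine by averaged
    structured subgradient descent, deterministic post-processing repair
    rules for decoded mentions, micro precision/recall/F-measure evaluation
    with exact span matching, and a seeded synthetic corpus generator so the
    whole pipeline can be trained and tested without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
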