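Package: medparts
Title: Medical Terminology Decomposition and Out-of-Vocabulary Word Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns vectors to out-of-vocabulary biomedical terms for any
    pre-trained word-embedding table by post-processing: lexical
    normalization, rule-based medical plural/singular inflection,
    prefix/root/suffix decomposition against meaning dictionaries with
    mean-vector encoding, and a unigram Viterbi subword segmenter as a final
    fallback. Includes an intrinsic-evaluation kit (cosine similarity,
    Spearman rank correlation, precision/recall/F1, coverage) for term-pair
    benchmarks, a reader for word2vec text embeddings, a tab-separated
    component-lexicon format with a shipped fixture lexicon, and a seeded
    generator of synthetic compound medical terms, toy embeddings and
    term-pair datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
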