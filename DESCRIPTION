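Package: semrank
Title: Semantic Re-Ranking of Text-Based Medical Image Retrieval Results
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-ranks text-based medical image retrieval results by fusing a
    BM25 first-pass score with a deep matching model built on Medical-Dependent
    Features (MDF). Documents and queries are mapped to ordered MDF
    annotations via lexicon matching, embedded through a semantic similarity
    matrix, transformed by a bank of twelve formula-defined retrieval filters
    through a convolution/ReLU/max-pool/fully-connected forward pass, matched
    by cosine similarity, and linearly fused with the normalized baseline
    score. Includes TREC-style run and qrels input/output, MAP and P@k
    evaluation with Wilcoxon signed-rank comparison, and a seeded synthetic
    collection generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
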