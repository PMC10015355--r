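Package: crossner
Title: Cross-Lingual Synthesis of Annotated Clinical NER Corpora by
    Translation and Annotation Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesizes annotated named-entity-recognition corpora in a
    target language from standoff-annotated source-language clinical text.
    The pipeline replaces de-identification masks with sampled surrogates
    while remapping character offsets, splits documents into annotated
    sentences, translates them through pluggable backends, aligns words,
    filters ill-aligned sentence pairs by the diagonality of the word
    mapping matrix, and projects character-level annotations onto the
    translations. Also ships a lightweight trainable transition-based
    IOB named-entity tagger (hash embeddings, convolutional context
    encoder, stateful greedy parser), entity/token/character-level
    evaluation with label-frequency-weighted totals, and a seeded
    synthetic-corpus generator so every stage is testable without
    access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
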