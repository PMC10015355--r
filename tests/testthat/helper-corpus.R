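# In-code fixtures shared by several test files.

# Small two-label training corpus with token-aligned gold spans; every
# sentence has one Drug and one Route entity.
tagged_training_corpus <- function(n = 10L) {
  drugs <- c("aspirin", "metformin", "warfarin", "insulin")
  routes <- c("orally", "iv", "topically")
  rows <- lapply(seq_len(n), function(i) {
    d <- drugs[(i %% length(drugs)) + 1]
    r <- routes[(i %% length(routes)) + 1]
    pre <- sprintf("Pt %d took ", i)
    mid <- " given "
    txt <- paste0(pre, d, mid, r, " today .")
    s1 <- nchar(pre)
    s2 <- s1 + nchar(d) + nchar(mid)
    tibble::tibble(
      doc_id = "d", sent_index = i - 1L, text = txt, doc_offset = 0L,
      annotations = list(annotation_tbl(
        c(s1, s2), c(s1 + nchar(d), s2 + nchar(r)),
        c("Drug", "Route"), c(d, r)
      ))
    )
  })
  dplyr::bind_rows(rows)
}

# Annotated sentence tibble straight from the synthetic-corpus generator.
fixture_sentences <- function(seed = 5L, n_documents = 6L, ...) {
  fx <- generate_masked_corpus(fixture_spec(seed = seed,
                                            n_documents = n_documents, ...))
  suppressMessages(drop_unannotated(split_sentences(fx$documents)))
}

all_annotation_keys <- function(sentences) {
  keys <- purrr::pmap(sentences[, c("doc_id", "sent_index", "annotations")],
                      function(doc_id, sent_index, annotations) {
    if (!nrow(annotations)) return(character())
    paste(doc_id, sent_index, annotations$label, annotations$surface)
  })
  sort(unlist(keys))
}
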