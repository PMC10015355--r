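test_that("standoff T-lines parse into validated annotations", {
  doc <- read_standoff("aspirin 81 mg", "T1\tDrug 0 7\taspirin")
  ann <- doc$annotations[[1]]
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$start, 0L)
  expect_equal(ann$end, 7L)
  expect_equal(ann$label, "Drug")
  expect_equal(ann$surface, "aspirin")

  empty <- read_standoff("aspirin 81 mg", "")
  expect_equal(nrow(empty$annotations[[1]]), 0L)
})

test_that("discontinuous spans split into contiguous fragments", {
  doc <- read_standoff("aspirin 81 mg", "T1\tDrug 0 7;8 10\taspirin 81")
  ann <- doc$annotations[[1]]
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$label, c("Drug", "Drug"))
  # fragments verified by slicing the text directly
  expect_equal(ann$surface, c(substr("aspirin 81 mg", 1, 7),
                              substr("aspirin 81 mg", 9, 10)))
})

test_that("standoff errors name the offending line, surfaces recomputed", {
  expect_error(read_standoff("abc", "T1\tnot-a-record"), "line 1")
  expect_error(read_standoff("abc", "T1\tDrug 0 99\tx"), "line 1")
  expect_warning(read_standoff("aspirin", "T1\tDrug 0 7\tASPIRIN"),
                 "differs from text slice")
  got <- suppressWarnings(read_standoff("aspirin", "T1\tDrug 0 7\tASPIRIN"))
  expect_equal(got$annotations[[1]]$surface, "aspirin")
})

test_that("relation and attribute records are skipped with a note", {
  expect_message(
    doc <- read_standoff("aspirin 81 mg",
                         "T1\tDrug 0 7\taspirin\nR1\tDose Arg1:T1 Arg2:T2\nA1\tNegated T1"),
    "2 relation/attribute"
  )
  expect_equal(nrow(doc$annotations[[1]]), 1L)
})

test_that("CoNLL output is IOB2 and round-trips", {
  s <- tibble::tibble(
    doc_id = "d", sent_index = 0L, text = "took aspirin", doc_offset = 0L,
    annotations = list(annotation_tbl(5, 12, "Drug", "aspirin"))
  )
  expect_equal(write_conll(s), "took\tO\naspirin\tB-Drug\n")

  s2 <- tibble::tibble(
    doc_id = "d", sent_index = 0L, text = "took 81 mg now", doc_offset = 0L,
    annotations = list(annotation_tbl(5, 10, "Strength", "81 mg"))
  )
  lines <- strsplit(write_conll(s2), "\n")[[1]]
  expect_equal(lines[2:3], c("81\tB-Strength", "mg\tI-Strength"))

  sents <- fixture_sentences()[1:3, ]
  back <- read_conll(write_conll(sents))
  expect_equal(nrow(back), 3L)
  for (i in 1:3) {
    expect_equal(back$annotations[[i]][, c("label", "surface")],
                 sents$annotations[[i]][, c("label", "surface")])
  }
})

test_that("annotations crossing token boundaries are rejected on write", {
  s <- tibble::tibble(
    doc_id = "d", sent_index = 0L, text = "took aspirin", doc_offset = 0L,
    annotations = list(annotation_tbl(5, 8, "Drug", "asp"))
  )
  expect_error(write_conll(s), "\\[5, 8\\)")
})

test_that("JSONL round trip is lossless and preserves per-label counts", {
  fx <- generate_masked_corpus(fixture_spec(seed = 21, n_documents = 30))
  docs <- fx$documents
  back <- read_jsonl(write_jsonl(docs))
  expect_equal(back$text, docs$text)
  expect_equal(back$doc_id, docs$doc_id)
  for (i in seq_len(nrow(docs))) {
    expect_equal(back$annotations[[i]], docs$annotations[[i]])
  }
  lab_in <- table(unlist(purrr::map(docs$annotations, "label")))
  lab_out <- table(unlist(purrr::map(back$annotations, "label")))
  expect_equal(lab_in, lab_out)
})

test_that("JSONL rejects bad spans with a position report", {
  expect_error(read_jsonl('{"doc_id":"d","text":"abc","entities":[[0,99,"Drug"]]}'),
               "line 1")
  expect_error(
    read_jsonl('{"doc_id":"d","text":"abcdef","entities":[[0,4,"Drug"],[2,6,"Form"]]}'),
    "overlapping"
  )
})

test_that("parsed surfaces always equal the text slice of their span", {
  fx <- generate_masked_corpus(fixture_spec(seed = 3, n_documents = 8))
  for (i in seq_len(nrow(fx$documents))) {
    ann <- fx$documents$annotations[[i]]
    doc <- read_standoff(fx$documents$text[i],
                         write_standoff(fx$documents[i, ]))
    expect_equal(doc$annotations[[1]], ann)
  }
})
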