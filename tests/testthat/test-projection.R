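test_that("whitespace tokenization yields exact character spans", {
  toks <- tokenize_with_offsets("Nehmen Sie täglich Aspirin")
  expect_equal(toks$start, c(0L, 7L, 11L, 19L))
  expect_equal(toks$end, c(6L, 10L, 18L, 26L))
  expect_equal(toks$token, c("Nehmen", "Sie", "täglich", "Aspirin"))
  expect_equal(nrow(tokenize_with_offsets("")), 0L)
  expect_equal(tokenize_with_offsets("x"),
               tibble::tibble(token = "x", start = 0L, end = 1L))
})

test_that("diagonality score matches hand-derived cases", {
  ident <- alignment_matrix(tibble::tibble(src = 0:2, tgt = 0:2), 3, 3)
  expect_equal(diagonality_score(ident), 0)

  anti <- alignment_matrix(tibble::tibble(src = 0:2, tgt = 2:0), 3, 3)
  expect_equal(diagonality_score(anti), mean(c(sqrt(2), 0, sqrt(2))),
               tolerance = 1e-12)

  rect <- alignment_matrix(tibble::tibble(src = c(0L, 0L, 1L),
                                          tgt = c(0L, 1L, 2L)), 2, 3)
  expect_equal(diagonality_score(rect), (1 / sqrt(5)) / 3, tolerance = 1e-12)

  expect_error(diagonality_score(matrix(0L, 2, 2)), "all-zero")
})

test_that("score equals the brute-force oracle on random binary matrices", {
  set.seed(404)
  for (rep in 1:200) {
    m <- random_link_matrix(12L)
    expect_equal(diagonality_score(m), brute_force_diagonality(m),
                 tolerance = 1e-9)
  }
})

test_that("score is invariant under transposition", {
  set.seed(77)
  for (rep in 1:50) {
    m <- random_link_matrix(10L)
    expect_equal(diagonality_score(m), diagonality_score(t(m)),
                 tolerance = 1e-12)
  }
})

test_that("adding an on-diagonal link never increases the score", {
  set.seed(12)
  for (rep in 1:30) {
    n <- sample(2:10, 1)
    m <- random_link_matrix(n)
    # a point exactly on the corner-to-corner line: (1,1) always qualifies
    m2 <- m
    m2[1, 1] <- 1L
    expect_lte(diagonality_score(m2), diagonality_score(m) + 1e-12)
  }
})

test_that("the filter rule keeps diagonal-like pairs and is monotone in t", {
  ident <- alignment_matrix(tibble::tibble(src = 0:2, tgt = 0:2), 3, 3)
  expect_true(passes_filter(ident, 1.8))

  corner <- alignment_matrix(tibble::tibble(src = 0L, tgt = 4L), 5, 5)
  expect_equal(diagonality_score(corner), 4 / sqrt(2), tolerance = 1e-12)
  expect_false(passes_filter(corner, 1.8))

  expect_false(passes_filter(matrix(0L, 3, 4), 1.8))

  set.seed(5)
  for (rep in 1:30) {
    m <- random_link_matrix(8L)
    t1 <- runif(1, 0, 3)
    t2 <- t1 + runif(1, 0, 2)
    if (passes_filter(m, t1)) expect_true(passes_filter(m, t2))
  }
})

test_that("annotations project through the word mapping at character level", {
  pair <- sentence_pair("Take aspirin daily", "Nehmen Sie täglich Aspirin",
                        tibble::tibble(src = c(0L, 0L, 1L, 2L),
                                       tgt = c(0L, 1L, 3L, 2L)))
  p <- project_annotation(list(start = 5L, end = 12L, label = "Drug"), pair)
  expect_equal(p$start, 19L)
  expect_equal(p$end, 26L)
  expect_equal(p$surface, "Aspirin")
  expect_equal(p$label, "Drug")

  # identity pair: span reproduced exactly
  idp <- sentence_pair("Take aspirin daily", "Take aspirin daily",
                       tibble::tibble(src = 0:2, tgt = 0:2))
  q <- project_annotation(list(start = 5L, end = 12L, label = "Drug"), idp)
  expect_equal(q$start, 5L)
  expect_equal(q$end, 12L)

  # unlinked span is discarded
  nolink <- sentence_pair("Take aspirin daily", "Nehmen Sie",
                          tibble::tibble(src = c(0L, 2L), tgt = c(0L, 1L)))
  expect_null(project_annotation(list(start = 5L, end = 12L, label = "Drug"),
                                 nolink))
})

test_that("projected spans stay inside the target with labels unchanged", {
  sents <- fixture_sentences(seed = 41, n_documents = 8)
  synth <- synthesize_corpus(sents, "reversible", "reversible")
  for (i in seq_len(nrow(synth$sentences))) {
    ann <- synth$sentences$annotations[[i]]
    n <- nchar(synth$sentences$text[i])
    if (!nrow(ann)) next
    expect_true(all(ann$start >= 0 & ann$end <= n))
    expect_true(all(ann$label %in% projected_labels()))
  }
  expect_lte(glance(synth)$annotations_out, glance(synth)$annotations_in)
})

test_that("reversible-mock projection maps surfaces to their _DE forms", {
  sents <- fixture_sentences(seed = 43, n_documents = 8)
  synth <- synthesize_corpus(sents, "reversible", "reversible")
  checked <- 0L
  for (i in seq_len(nrow(synth$sentences))) {
    src_txt <- synth$sentences$source_text[i]
    ann_in <- sents$annotations[[match(paste(synth$sentences$doc_id[i],
                                             synth$sentences$sent_index[i]),
                                       paste(sents$doc_id, sents$sent_index))]]
    ann_out <- synth$sentences$annotations[[i]]
    expect_equal(nrow(ann_out), nrow(ann_in))
    # projected spans are re-sorted by target position; fixture sentences
    # carry each label at most once, so pair the annotations by label
    expect_setequal(ann_out$label, ann_in$label)
    for (r in seq_len(nrow(ann_out))) {
      rin <- match(ann_out$label[r], ann_in$label)
      toks_in <- tokenize_with_offsets(ann_in$surface[rin])$token
      toks_out <- tokenize_with_offsets(ann_out$surface[r])$token
      # hull rule: when the span's image is contiguous, surfaces correspond
      if (length(toks_out) == length(toks_in)) {
        expect_setequal(toks_out, paste0(toks_in, "_DE"))
        checked <- checked + 1L
      }
    }
  }
  expect_gt(checked, 20L)
})

test_that("label blacklist removes Reason and ADE before projection", {
  s <- tibble::tibble(
    doc_id = "d", sent_index = 0L, text = "aspirin for pain relief now",
    doc_offset = 0L,
    annotations = list(annotation_tbl(c(0L, 12L), c(7L, 16L),
                                      c("Drug", "Reason"),
                                      c("aspirin", "pain")))
  )
  synth <- synthesize_corpus(s, "identity", "identity")
  expect_equal(synth$sentences$annotations[[1]]$label, "Drug")
})

test_that("filter_pairs scores pairs from explicit gold links", {
  sents <- fixture_sentences(seed = 47, n_documents = 10)
  pp <- make_pseudo_parallel(sents, seed = 47, scramble_fraction = 0.25)
  fp <- filter_pairs(pp, t = 1.8)
  expect_equal(!fp$kept, fp$scrambled)
  expect_true(all(fp$score[!fp$scrambled] < 1.8))
})
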