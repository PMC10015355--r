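span <- function(sid, start, end, label) {
  tibble::tibble(sentence_id = sid, start = start, end = end, label = label)
}

test_that("entity scores follow exact-match counting", {
  g <- span(1L, 0L, 5L, "Drug")
  expect_equal(unname(unlist(entity_prf(g, g)[1, c("precision", "recall", "f1")])),
               c(100, 100, 100))

  p <- dplyr::bind_rows(span(1L, 0L, 5L, "Drug"), span(1L, 6L, 8L, "Drug"))
  rep <- entity_prf(g, p)
  drug <- rep[rep$tag == "Drug", ]
  expect_equal(drug$precision, 50)
  expect_equal(drug$recall, 100)
  expect_equal(drug$f1, 2 * 50 * 100 / 150, tolerance = 1e-9)

  none <- entity_prf(g, g[0, ])
  expect_equal(unname(unlist(none[1, c("precision", "recall", "f1")])),
               c(0, 0, 0))
})

test_that("entity scores agree with a brute-force matcher on random sets", {
  set.seed(909)
  for (rep in 1:25) {
    mk <- function(n) span(sample(1:3, n, TRUE),
                           s <- sample(0:20, n, TRUE) * 10L,
                           s + sample(1:5, n, TRUE),
                           sample(c("Drug", "Form"), n, TRUE))
    g <- mk(sample(1:8, 1))
    p <- mk(sample(1:8, 1))
    ours <- glance(entity_prf(g, p))
    # micro-averaged oracle equals weighted per-tag averaging only in
    # aggregate TP terms; compare per-tag instead
    for (tag in unique(c(g$label, p$label))) {
      o <- brute_force_entity_prf(g[g$label == tag, ], p[p$label == tag, ])
      r <- entity_prf(g, p)
      r <- r[r$tag == tag, ]
      expect_equal(r$precision, o$precision, tolerance = 1e-9)
      expect_equal(r$recall, o$recall, tolerance = 1e-9)
    }
  }
})

test_that("token-wise IOB evaluation pools B and I per label", {
  rep <- token_iob_eval(c("B-Drug", "I-Drug", "O"), c("B-Drug", "O", "O"))
  drug <- rep[rep$tag == "Drug", ]
  expect_equal(drug$precision, 100)
  expect_equal(drug$recall, 50)
  expect_equal(drug$f1, 200 / 3, tolerance = 1e-9)

  same <- token_iob_eval(c("B-Drug", "O"), c("B-Drug", "O"))
  expect_equal(same[same$tag == "Drug", ]$f1, 100)

  allo <- token_iob_eval(c("O", "O"), c("O", "O"))
  expect_equal(allo$tag, "Total")

  expect_error(token_iob_eval(c("O"), c("O", "O")), "length")
})

test_that("character-wise label F1 counts per-character assignments", {
  g <- span(1L, 0L, 7L, "Drug")
  p <- span(1L, 0L, 4L, "Drug")
  rep <- char_label_f1(g, p)
  drug <- rep[rep$tag == "Drug", ]
  expect_equal(drug$precision, 100)
  expect_equal(drug$recall, 100 * 4 / 7, tolerance = 1e-9)
  expect_equal(drug$f1, 2 * 100 * (400 / 7) / (100 + 400 / 7), tolerance = 1e-6)

  expect_equal(char_label_f1(g, g)[1, ]$f1, 100)
  expect_equal(char_label_f1(g, span(1L, 10L, 12L, "Drug"))[1, ]$f1, 0)

  # invariant to splitting a gold span into adjacent same-label spans
  gsplit <- dplyr::bind_rows(span(1L, 0L, 3L, "Drug"), span(1L, 3L, 7L, "Drug"))
  expect_equal(tidy(char_label_f1(gsplit, p)), tidy(char_label_f1(g, p)))

  expect_error(
    char_label_f1(dplyr::bind_rows(span(1L, 0L, 4L, "Drug"),
                                   span(1L, 2L, 6L, "Form")), p),
    "conflicting"
  )
})

test_that("split sizes follow the rounding contract", {
  s <- split_dataset(8599, seed = 1)
  expect_equal(lengths(s), c(train = 6879L, val = 860L, test = 860L))
  expect_equal(lengths(split_dataset(10, seed = 1)),
               c(train = 8L, val = 1L, test = 1L))
  expect_equal(lengths(split_dataset(100, seed = 1)),
               c(train = 80L, val = 10L, test = 10L))
  # exact disjoint partition, seeded
  s2 <- split_dataset(100, seed = 9)
  expect_setequal(unlist(s2), 1:100)
  expect_equal(split_dataset(100, seed = 9), s2)
  expect_false(identical(split_dataset(100, seed = 10), s2))
})

test_that("dataset statistics match generator bookkeeping", {
  expect_equal(dataset_stats(tibble::tibble(text = character(),
                                            annotations = list()))$n_annotations, 0L)
  fx <- generate_masked_corpus(fixture_spec(seed = 19, n_documents = 12))
  sents <- suppressMessages(drop_unannotated(split_sentences(fx$documents)))
  st <- dataset_stats(sents)
  expect_equal(as.vector(st$per_label), as.vector(fx$bookkeeping$per_label))
  expect_equal(st$n_annotations, fx$bookkeeping$n_annotations)
  expect_equal(st$n_annotations, sum(st$per_label))
})

test_that("weighted totals sit inside the per-tag range", {
  set.seed(31)
  for (rep in 1:20) {
    g <- dplyr::bind_rows(span(1L, 0L, 5L, "Drug"), span(1L, 10L, 15L, "Form"),
                          span(2L, 0L, 5L, "Drug"))
    p <- g[sample(3, sample(3, 1)), ]
    r <- entity_prf(g, p)
    per <- r[r$tag != "Total", ]
    tot <- r[r$tag == "Total", ]
    expect_gte(tot$f1, min(per$f1) - 1e-9)
    expect_lte(tot$f1, max(per$f1) + 1e-9)
  }
  single <- entity_prf(span(1L, 0L, 5L, "Drug"), span(1L, 0L, 5L, "Drug"))
  expect_equal(single[single$tag == "Total", ]$f1,
               single[single$tag == "Drug", ]$f1)
})

test_that("model deltas are per-tag F1 differences", {
  a <- reference_report_german()
  expect_equal(compare_models(a, a)$delta, rep(0, 8))
  cm <- compare_models(a, reference_report_english())
  expect_equal(cm$delta[cm$tag == "Drug"], -14.73, tolerance = 1e-9)
  b <- reference_report_english()
  b$tag[1] <- "Other"
  expect_error(compare_models(a, b), "identical label sets")
})
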