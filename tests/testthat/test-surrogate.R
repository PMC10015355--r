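test_that("mask detection finds typed placeholders at exact offsets", {
  m <- detect_masks("DOB [**Date**].")
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 4L)
  expect_equal(m$end, 14L)
  expect_equal(m$mask_type, "date")

  expect_equal(nrow(detect_masks("no placeholders here")), 0L)

  two <- detect_masks("[**Name**][**Year**]")
  expect_equal(nrow(two), 2L)
  expect_equal(two$mask_type, c("name", "year"))
  expect_true(all(two$start == c(0L, 10L)))

  expect_equal(detect_masks("[**Gibberish Keyword**]")$mask_type, "other")
})

test_that("unbalanced delimiters raise an error with a position", {
  expect_error(detect_masks("open [**Name here"), "offset 5")
})

test_that("replacement remaps offsets and preserves disjoint surfaces", {
  doc <- document_tbl("d1", "See [**Name**]: aspirin 81 mg",
                      list(annotation_tbl(16, 23, "Drug", "aspirin")))
  samplers <- builtin_samplers(1)
  samplers$name <- function(width) "Kim Lee"
  out <- replace_masks(doc, samplers)
  expect_equal(out$text, "See Kim Lee: aspirin 81 mg")
  ann <- out$annotations[[1]]
  expect_equal(ann$start, 13L)
  expect_equal(ann$end, 20L)
  expect_equal(ann$surface, "aspirin")
})

test_that("documents without masks come back unchanged with identity map", {
  doc <- document_tbl("d", "aspirin 81 mg",
                      list(annotation_tbl(0, 7, "Drug", "aspirin")))
  out <- replace_masks(doc, builtin_samplers(1))
  expect_equal(out$text, doc$text)
  expect_equal(out$annotations[[1]], doc$annotations[[1]])
  omap <- out$offset_map[[1]]
  expect_equal(map_offset(omap, c(0L, 5L, 12L)), c(0L, 5L, 12L))
})

test_that("annotations before the first mask keep their offsets", {
  doc <- document_tbl("d", "aspirin for [**First Name**]",
                      list(annotation_tbl(0, 7, "Drug", "aspirin")))
  out <- replace_masks(doc, builtin_samplers(1))
  expect_equal(out$annotations[[1]]$start, 0L)
  expect_equal(out$annotations[[1]]$end, 7L)
})

test_that("annotations straddling a mask boundary are an error", {
  doc <- document_tbl("d", "ab [**Name**] cd",
                      list(annotation_tbl(0, 8, "Drug", "ab [**Na")))
  expect_error(replace_masks(doc, builtin_samplers(1)), "straddles")
})

test_that("annotations inside a mask are retargeted to the surrogate", {
  doc <- document_tbl("d", "x [**Phone Number**] y",
                      list(annotation_tbl(5, 10, "Dosage", "Phone")))
  out <- replace_masks(doc, builtin_samplers(1))
  ann <- out$annotations[[1]]
  expect_equal(ann$surface, out$masks[[1]]$surrogate)
})

test_that("samplers are seeded, reproducible streams with typed output", {
  a <- builtin_samplers(7)
  b <- builtin_samplers(7)
  expect_equal(replicate(5, a$name(0)), replicate(5, b$name(0)))
  expect_equal(replicate(5, a$date(0)), replicate(5, b$date(0)))

  # date output parses under at least one configured format
  fmts <- c("%m/%d/%Y", "%Y-%m-%d", "%d %b %Y")
  for (d in replicate(10, a$date(0))) {
    parsed <- suppressWarnings(lapply(fmts, function(f) as.Date(d, format = f)))
    expect_true(any(!is.na(unlist(parsed))))
  }

  # numeric surrogates match the mask width
  widths <- nchar(replicate(1000, a$numeric(3)))
  expect_true(all(widths == 3L))
  expect_true(all(grepl("^[0-9]+$", replicate(50, a$numeric(4)))))
})

test_that("offset map is order-preserving and non-mask text is conserved", {
  fx <- generate_masked_corpus(fixture_spec(seed = 13, n_documents = 10,
                                            mask_rate = 0.8))
  out <- replace_masks(fx$documents, builtin_samplers(13))
  for (i in seq_len(nrow(out))) {
    omap <- out$offset_map[[i]]
    masks <- out$masks[[i]]
    old_text <- fx$documents$text[i]
    # probe offsets strictly outside replaced regions
    pos <- setdiff(0:(nchar(old_text) - 1L),
                   unlist(purrr::map2(masks$start, masks$end, ~ seq(.x, .y - 1L))))
    mapped <- map_offset(omap, pos)
    expect_true(all(diff(mapped) > 0))
    # unreplaced characters survive byte for byte
    expect_equal(strsplit(out$text[i], "")[[1]][mapped + 1L],
                 strsplit(old_text, "")[[1]][pos + 1L])
    # annotation count conserved
    expect_equal(nrow(out$annotations[[i]]), nrow(fx$documents$annotations[[i]]))
  }
})

test_that("replacement is deterministic under a fixed seed", {
  fx <- generate_masked_corpus(fixture_spec(seed = 2, n_documents = 5,
                                            mask_rate = 0.6))
  one <- replace_masks(fx$documents, builtin_samplers(9))
  two <- replace_masks(fx$documents, builtin_samplers(9))
  expect_equal(one$text, two$text)
})
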