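# Seeded synthetic-corpus generator: templated clinical-style documents
# with typed entities, de-identification masks, and deterministic
# pseudo-translations with gold word alignments, so every pipeline stage
# is testable without access-restricted clinical data or external models.

#' Specification of a synthetic fixture corpus
#'
#' @param seed RNG seed; a fixed seed yields a byte-identical corpus.
#' @param n_documents Number of documents.
#' @param sentences_range Min/max sentences per document.
#' @param mask_rate Probability that a sentence carries a de-identification
#'   mask.
#' @param unannotated_rate Probability that a sentence carries no entity
#'   (these are the sentences later removed by [drop_unannotated()]).
#' @param scramble_fraction Fraction of sentence pairs given adversarial
#'   long-range (reversal) permutations in [make_pseudo_parallel()],
#'   designed to exceed the diagonality threshold.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_documents = 10L,
                         sentences_range = c(3L, 8L), mask_rate = 0.3,
                         unannotated_rate = 0.3, scramble_fraction = 0) {
  stopifnot(mask_rate >= 0, mask_rate <= 1, unannotated_rate >= 0,
            unannotated_rate <= 1, scramble_fraction >= 0, scramble_fraction <= 1)
  structure(list(seed = as.integer(seed), n_documents = as.integer(n_documents),
                 sentences_range = as.integer(sentences_range),
                 mask_rate = mask_rate, unannotated_rate = unannotated_rate,
                 scramble_fraction = scramble_fraction),
            class = "fixture_spec")
}

fixture_lexicon <- function() {
  list(
    Drug = c("aspirin", "metformin", "lisinopril", "warfarin", "ibuprofen",
             "atorvastatin", "amoxicillin", "insulin"),
    Strength = c("81 mg", "500 mg", "10 mg", "5 mg", "20 mg", "250 mg"),
    Route = c("orally", "iv", "topically", "subcutaneously"),
    Frequency = c("daily", "twice daily", "every 6 hours", "weekly", "at bedtime"),
    Duration = c("for 7 days", "for 2 weeks", "for 1 month", "for 3 days"),
    Form = c("tablet", "capsule", "solution", "patch"),
    Dosage = c("one", "two", "three", "half")
  )
}

MASK_KEYWORDS <- c("First Name", "Date", "Year", "Phone Number", "MRN",
                   "Hospital Address")

# One sentence: clinical-style template with typed entity slots; returns
# text + annotation table. Mask placeholders use the MIMIC-style dialect.
fixture_sentence <- function(lex, annotated, masked) {
  prefix <- if (masked) {
    paste0("Seen by [**", sample(MASK_KEYWORDS, 1), "**] on admission. ")
  } else ""
  if (!annotated) {
    filler <- sample(c("Patient resting comfortably with no complaints today.",
                       "Vital signs stable and reviewed this morning.",
                       "Plan discussed with the care team at length."), 1)
    txt <- paste0(prefix, filler)
    return(list(text = txt, annotations = empty_annotations()))
  }
  slots <- c("Dosage", "Form", "Drug", "Strength", "Route", "Frequency", "Duration")
  use <- slots[c(stats::runif(2) < 0.5, TRUE, stats::runif(4) < 0.6)]
  words <- c("Pt took")
  starts <- integer(); ends <- integer(); labels <- character()
  cursor <- nchar_cp(prefix) + nchar_cp("Pt took")
  for (s in use) {
    value <- sample(lex[[s]], 1)
    words <- c(words, value)
    starts <- c(starts, cursor + 1L)
    ends <- c(ends, cursor + 1L + nchar_cp(value))
    labels <- c(labels, s)
    cursor <- cursor + 1L + nchar_cp(value)
  }
  # final period is its own token so every entity stays token-aligned
  txt <- paste0(prefix, paste(words, collapse = " "), " .")
  list(text = txt,
       annotations = annotation_tbl(starts, ends, labels,
                                    slice_text(txt, starts, ends)))
}

#' Generate a masked, annotated synthetic corpus
#'
#' Documents are built from templated clinical-style sentences with typed
#' entities from the 7-label medication set, de-identification masks
#' inserted at `mask_rate`, and a fraction of unannotated filler
#' sentences. Gold bookkeeping records expected per-label entity counts,
#' mask counts, and the unannotated-sentence count, for cross-module
#' oracle tests.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `documents` (document tibble) and `bookkeeping`
#'   (list: `per_label`, `n_annotations`, `n_masks`, `n_sentences`,
#'   `n_unannotated`).
#' @export
generate_masked_corpus <- function(spec) {
  withr_seed(spec$seed, {
    lex <- fixture_lexicon()
    n_masks <- 0L; n_sent <- 0L; n_unann <- 0L
    labels_all <- character()
    docs <- purrr::map(seq_len(spec$n_documents), function(d) {
      k <- sample(seq(spec$sentences_range[1], spec$sentences_range[2]), 1)
      parts <- purrr::map(seq_len(k), function(i) {
        annotated <- stats::runif(1) >= spec$unannotated_rate
        masked <- stats::runif(1) < spec$mask_rate
        fixture_sentence(lex, annotated, masked)
      })
      n_sent <<- n_sent + k
      offset <- 0L
      anns <- list(); text_parts <- character()
      for (ptx in parts) {
        if (!nrow(ptx$annotations)) n_unann <<- n_unann + 1L
        n_masks <<- n_masks + (grepl("[**", ptx$text, fixed = TRUE))
        a <- ptx$annotations
        if (nrow(a)) {
          a$start <- a$start + offset; a$end <- a$end + offset
          anns[[length(anns) + 1L]] <- a
          labels_all <<- c(labels_all, a$label)
        }
        text_parts <- c(text_parts, ptx$text)
        offset <- offset + nchar_cp(ptx$text) + 1L
      }
      text <- paste(text_parts, collapse = " ")
      ann <- if (length(anns)) dplyr::bind_rows(anns) else empty_annotations()
      if (nrow(ann)) ann$surface <- slice_text(text, ann$start, ann$end)
      document_tbl(sprintf("doc%03d", d), text, list(ann))
    })
    list(
      documents = dplyr::bind_rows(docs),
      bookkeeping = list(
        per_label = if (length(labels_all)) table(labels_all) else table(character()),
        n_annotations = length(labels_all),
        n_masks = n_masks,
        n_sentences = n_sent,
        n_unannotated = n_unann
      )
    )
  })
}

# Deterministic pseudo-translation of one token vector: suffix every token
# with "_DE" and apply either a local adjacent-pair swap permutation
# (plausible, low diagonality by construction: a token never moves more
# than one position, bounding each link's distance to the diagonal by
# 1/sqrt(2) in square matrices) or, for scrambled pairs, a full reversal
# whose diagonality grows linearly with length.
pseudo_translate_tokens <- function(tokens, scramble) {
  n <- length(tokens)
  perm <- if (scramble) rev(seq_len(n)) else {
    perm <- seq_len(n)
    if (n >= 2L) {
      swap <- stats::runif(floor(n / 2)) < 0.5
      for (k in which(swap)) {
        i <- 2L * k - 1L
        perm[c(i, i + 1L)] <- perm[c(i + 1L, i)]
      }
    }
    perm
  }
  list(tokens = paste0(tokens, "_DE")[perm], perm = perm)
}

#' Build pseudo-parallel sentence pairs with gold alignments
#'
#' Each sentence is deterministically "translated" (token suffixing plus
#' seeded local reordering) with the gold link set recorded exactly. A
#' `scramble_fraction` of pairs instead receive a full reversal — an
#' adversarial long-range permutation whose diagonality score exceeds the
#' filter threshold for sentences of nine or more tokens. Reversal
#' candidates are therefore restricted to such sentences.
#'
#' @param sentences A sentence tibble.
#' @param seed RNG seed.
#' @param scramble_fraction Fraction of eligible pairs to scramble.
#' @return A tibble `doc_id`, `sent_index`, `source`, `target`, `links`
#'   (list-column of gold link tibbles), `scrambled` (logical).
#' @export
make_pseudo_parallel <- function(sentences, seed = 1L, scramble_fraction = 0) {
  withr_seed(seed, {
    n <- nrow(sentences)
    tok <- purrr::map(sentences$text, ~ tokenize_with_offsets(.x)$token)
    eligible <- which(purrr::map_int(tok, length) >= 9L)
    n_scramble <- round(scramble_fraction * n)
    if (n_scramble > length(eligible)) {
      rlang::abort(sprintf(
        "cannot scramble %d pairs: only %d sentences have >= 9 tokens",
        n_scramble, length(eligible)))
    }
    scrambled <- rep(FALSE, n)
    scrambled[sample(eligible, n_scramble)] <- TRUE
    rows <- purrr::map(seq_len(n), function(i) {
      tr <- pseudo_translate_tokens(tok[[i]], scrambled[i])
      # source token tr$perm[j] lands at target position j
      links <- tibble::tibble(src = tr$perm - 1L, tgt = seq_along(tr$perm) - 1L)
      tibble::tibble(doc_id = sentences$doc_id[i],
                     sent_index = sentences$sent_index[i],
                     source = sentences$text[i],
                     target = paste(tr$tokens, collapse = " "),
                     links = list(links), scrambled = scrambled[i])
    })
    dplyr::bind_rows(rows)
  })
}

#' Emit a fixture corpus to disk in every pipeline format
#'
#' Writes per-document `.txt`/`.ann` standoff files, a JSONL span dataset,
#' bitext and Pharaoh alignment files for the pseudo-parallel pairs, and a
#' bookkeeping JSON.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the bookkeeping list.
#' @export
write_fixture_corpus <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- generate_masked_corpus(spec)
  purrr::pwalk(fx$documents, function(doc_id, text, annotations, ...) {
    writeLines(text, file.path(dir, paste0(doc_id, ".txt")), useBytes = TRUE)
    one <- document_tbl(doc_id, text, list(annotations))
    writeLines(write_standoff(one), file.path(dir, paste0(doc_id, ".ann")),
               useBytes = TRUE)
  })
  writeLines(write_jsonl(fx$documents), file.path(dir, "corpus.jsonl"),
             useBytes = TRUE)
  sents <- drop_unannotated(split_sentences(fx$documents))
  pairs <- make_pseudo_parallel(sents, seed = spec$seed,
                                scramble_fraction = spec$scramble_fraction)
  writeLines(write_bitext(pairs), file.path(dir, "bitext.txt"), useBytes = TRUE)
  writeLines(purrr::map_chr(pairs$links, format_pharaoh),
             file.path(dir, "alignments.pharaoh"), useBytes = TRUE)
  bk <- fx$bookkeeping
  bk$per_label <- as.list(bk$per_label)
  jsonlite::write_json(bk, file.path(dir, "bookkeeping.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(fx$bookkeeping)
}
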