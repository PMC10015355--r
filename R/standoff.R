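#' Read a brat/n2c2 standoff document
#'
#' Parses a `.txt` + `.ann` pair in brat standoff form. Only entity (`T`)
#' lines are read; relation (`R`) and attribute (`A`) records are ignored
#' with a logged count. Discontinuous spans (`start end;start end`) are
#' split into contiguous fragments, each inheriting the label. Surfaces are
#' recomputed from the text; a mismatch with the surface stored in the
#' `.ann` file is reported as a warning and the recomputed slice wins.
#'
#' @param txt_content Document text as a single string.
#' @param ann_content Standoff annotation content as a single string
#'   (possibly empty).
#' @param doc_id Identifier to assign to the document.
#' @return A one-row document tibble (see [document_tbl()]).
#' @export
read_standoff <- function(txt_content, ann_content, doc_id = "doc") {
  stopifnot(is.character(txt_content), length(txt_content) == 1L)
  lines <- strsplit(ann_content, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]

  skipped <- sum(grepl("^[RA]", lines))
  if (skipped > 0L) {
    rlang::inform(sprintf("read_standoff: ignoring %d relation/attribute records", skipped))
  }
  tlines <- grep("^T", lines)

  frags <- purrr::map(tlines, function(i) {
    parse_standoff_tline(lines[i], i, txt_content, doc_id)
  })
  ann <- if (length(frags)) dplyr::bind_rows(frags) else empty_annotations()
  ann <- dplyr::arrange(ann, .data$start, .data$end)
  document_tbl(doc_id = doc_id, text = txt_content, annotations = list(ann))
}

parse_standoff_tline <- function(line, lineno, text, doc_id) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) < 2L) {
    rlang::abort(sprintf("malformed standoff line %d: '%s'", lineno, line))
  }
  mid <- parts[2]
  m <- regmatches(mid, regexec("^(\\S+) ([0-9; ]+)$", mid))[[1]]
  if (length(m) != 3L) {
    rlang::abort(sprintf("malformed standoff line %d: cannot parse '%s'", lineno, mid))
  }
  label <- m[2]
  spans <- strsplit(m[3], ";", fixed = TRUE)[[1]]
  bounds <- purrr::map(spans, function(sp) {
    nums <- suppressWarnings(as.integer(strsplit(trimws(sp), " +")[[1]]))
    if (length(nums) != 2L || anyNA(nums)) {
      rlang::abort(sprintf("malformed span on standoff line %d: '%s'", lineno, sp))
    }
    nums
  })
  n <- nchar_cp(text)
  out <- purrr::map(bounds, function(b) {
    if (b[1] < 0L || b[2] <= b[1] || b[2] > n) {
      rlang::abort(sprintf(
        "standoff line %d: span [%d, %d) invalid for text of length %d",
        lineno, b[1], b[2], n
      ))
    }
    tibble::tibble(start = b[1], end = b[2], label = label,
                   surface = slice_text(text, b[1], b[2]))
  })
  out <- dplyr::bind_rows(out)
  stored <- if (length(parts) >= 3L) parts[3] else NA_character_
  recomputed <- paste(out$surface, collapse = " ")
  if (!is.na(stored) && stored != recomputed) {
    rlang::warn(sprintf(
      "standoff line %d in '%s': stored surface '%s' differs from text slice '%s'; using slice",
      lineno, doc_id, stored, recomputed
    ))
  }
  out
}

#' Write a document's annotations as brat standoff T-lines
#'
#' @param document A one-row document tibble.
#' @return Standoff `.ann` content as a single string.
#' @export
write_standoff <- function(document) {
  ann <- document$annotations[[1]]
  if (nrow(ann) == 0L) return("")
  paste0(sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(ann)),
                 ann$label, ann$start, ann$end, ann$surface),
         collapse = "\n")
}

#' Serialize sentences with annotations to two-column CoNLL IOB2
#'
#' Tokens are produced by [tokenize_with_offsets()]; each line is
#' `token<TAB>tag` with IOB2 tags (every entity opens with `B-`), sentences
#' separated by a blank line. Annotations must align with token boundaries.
#'
#' @param sentences A sentence tibble (see [split_sentences()]) with
#'   columns `text` and `annotations`.
#' @return CoNLL content as a single string.
#' @export
write_conll <- function(sentences) {
  blocks <- purrr::map2_chr(sentences$text, sentences$annotations, function(text, ann) {
    toks <- tokenize_with_offsets(text)
    tags <- spans_to_iob(ann, toks)
    paste(paste0(toks$token, "\t", tags), collapse = "\n")
  })
  paste0(paste(blocks, collapse = "\n\n"), "\n")
}

#' Parse two-column CoNLL IOB content back into sentences
#'
#' Reconstructs sentence texts by joining tokens with single spaces (token
#' offsets are re-derived), and decodes IOB tags to character spans.
#'
#' @param text CoNLL content as a single string.
#' @param doc_id Document id to assign.
#' @return A sentence tibble with columns `doc_id`, `sent_index`, `text`,
#'   `doc_offset`, `annotations`.
#' @export
read_conll <- function(text, doc_id = "doc") {
  blocks <- strsplit(trimws(text, which = "right"), "\n\n", fixed = TRUE)[[1]]
  rows <- purrr::imap(blocks, function(block, i) {
    lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad)) {
      rlang::abort(sprintf("malformed CoNLL line in sentence %d: '%s'", i, lines[bad[1]]))
    }
    tokens <- purrr::map_chr(parts, 1)
    tags <- purrr::map_chr(parts, 2)
    sent_text <- paste(tokens, collapse = " ")
    toks <- tokenize_with_offsets(sent_text)
    ann <- iob_to_spans(tags, toks, sent_text)
    tibble::tibble(doc_id = doc_id, sent_index = i - 1L, text = sent_text,
                   doc_offset = 0L, annotations = list(ann))
  })
  dplyr::bind_rows(rows)
}

# IOB2 encoding of character spans over a token table; errors if a span
# crosses a token boundary.
spans_to_iob <- function(ann, toks) {
  tags <- rep("O", nrow(toks))
  if (nrow(ann) == 0L) return(tags)
  for (r in seq_len(nrow(ann))) {
    inside <- which(toks$start < ann$end[r] & toks$end > ann$start[r])
    if (length(inside) == 0L ||
        toks$start[inside[1]] != ann$start[r] ||
        toks$end[inside[length(inside)]] != ann$end[r]) {
      rlang::abort(sprintf(
        "annotation [%d, %d) '%s' does not align with token boundaries",
        ann$start[r], ann$end[r], ann$label[r]
      ))
    }
    tags[inside] <- paste0("I-", ann$label[r])
    tags[inside[1]] <- paste0("B-", ann$label[r])
  }
  tags
}

# Decode an IOB (1 or 2) tag sequence over a token table to character spans.
iob_to_spans <- function(tags, toks, text) {
  starts <- integer(); ends <- integer(); labels <- character()
  open_label <- NULL; open_start <- NA_integer_; open_end <- NA_integer_
  close_open <- function() {
    if (!is.null(open_label)) {
      starts <<- c(starts, open_start); ends <<- c(ends, open_end)
      labels <<- c(labels, open_label)
    }
    open_label <<- NULL
  }
  for (k in seq_along(tags)) {
    tag <- tags[k]
    if (tag == "O") {
      close_open()
    } else if (startsWith(tag, "B-")) {
      close_open()
      open_label <- substring(tag, 3); open_start <- toks$start[k]; open_end <- toks$end[k]
    } else if (startsWith(tag, "I-")) {
      lab <- substring(tag, 3)
      if (!is.null(open_label) && identical(open_label, lab)) {
        open_end <- toks$end[k]
      } else {
        close_open()
        open_label <- lab; open_start <- toks$start[k]; open_end <- toks$end[k]
      }
    } else {
      rlang::abort(sprintf("invalid IOB tag '%s'", tag))
    }
  }
  close_open()
  if (length(starts) == 0L) return(empty_annotations())
  annotation_tbl(starts, ends, labels, slice_text(text, starts, ends))
}

#' Write documents as JSONL span records
#'
#' One JSON record per line with fields `doc_id`, `text` and `entities`,
#' the latter a list of `[start, end, label]` triples. Lossless round trip
#' through [read_jsonl()].
#'
#' @param documents A document tibble.
#' @return JSONL content as a single string.
#' @export
write_jsonl <- function(documents) {
  lines <- purrr::pmap_chr(documents, function(doc_id, text, annotations, ...) {
    ents <- purrr::pmap(annotations[, c("start", "end", "label")],
                        function(start, end, label) list(start, end, label))
    jsonlite::toJSON(list(doc_id = doc_id, text = text, entities = ents),
                     auto_unbox = TRUE)
  })
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Read JSONL span records into a document tibble
#'
#' Records with spans past the text end or with overlapping spans are
#' rejected with a position report.
#'
#' @param text JSONL content as a single string.
#' @return A document tibble.
#' @export
read_jsonl <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  rows <- purrr::imap(lines, function(line, i) {
    rec <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    ents <- rec$entities %||% list()
    ann <- if (length(ents)) {
      annotation_tbl(
        start = purrr::map_int(ents, ~ as.integer(.x[[1]])),
        end = purrr::map_int(ents, ~ as.integer(.x[[2]])),
        label = purrr::map_chr(ents, ~ as.character(.x[[3]])),
        surface = {
          s <- purrr::map_int(ents, ~ as.integer(.x[[1]]))
          e <- purrr::map_int(ents, ~ as.integer(.x[[2]]))
          if (any(e > nchar_cp(rec$text))) {
            rlang::abort(sprintf("JSONL line %d: span past text end", i))
          }
          slice_text(rec$text, s, e)
        }
      )
    } else empty_annotations()
    if (nrow(ann) > 1L && any(ann$start[-1L] < ann$end[-nrow(ann)])) {
      k <- which(ann$start[-1L] < ann$end[-nrow(ann)])[1]
      rlang::abort(sprintf(
        "JSONL line %d: overlapping spans at [%d, %d) and [%d, %d)",
        i, ann$start[k], ann$end[k], ann$start[k + 1L], ann$end[k + 1L]
      ))
    }
    document_tbl(rec$doc_id %||% sprintf("doc%d", i), rec$text, list(ann))
  })
  dplyr::bind_rows(rows)
}
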