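#' Split documents into sentences, localizing annotations
#'
#' Splits each document at boundaries proposed by a pluggable splitter
#' strategy and re-bases annotations to sentence-relative offsets. The
#' sentence spans tile the whole document text, so concatenating the
#' sentence texts reconstructs the document exactly. A proposed boundary
#' that would cut through an annotation is suppressed, merging the two
#' sentences so every annotation lies whole inside one sentence.
#'
#' @param documents A document tibble.
#' @param splitter A function `f(text)` returning the 0-based end offsets
#'   of the proposed sentences; offsets must be increasing and the last
#'   must equal the text length (covering boundaries). Default:
#'   [rule_splitter()].
#' @return A sentence tibble with columns `doc_id`, `sent_index`, `text`,
#'   `doc_offset`, `annotations` (sentence-relative).
#' @export
split_sentences <- function(documents, splitter = rule_splitter) {
  rows <- purrr::pmap(documents[, c("doc_id", "text", "annotations")],
                      split_document_one, splitter = splitter)
  dplyr::bind_rows(rows)
}

split_document_one <- function(doc_id, text, annotations, splitter) {
  n <- nchar_cp(text)
  if (n == 0L) {
    return(tibble::tibble(doc_id = character(), sent_index = integer(),
                          text = character(), doc_offset = integer(),
                          annotations = list()))
  }
  ends <- as.integer(splitter(text))
  if (length(ends) == 0L || is.unsorted(ends, strictly = TRUE) ||
      ends[length(ends)] != n || any(ends <= 0L)) {
    rlang::abort("splitter returned non-covering boundaries")
  }
  # suppress boundaries that cut an annotation (merge-on-straddle)
  if (nrow(annotations)) {
    cuts <- purrr::map_lgl(ends, function(e)
      any(annotations$start < e & annotations$end > e))
    ends <- ends[!cuts | ends == n]
  }
  starts <- c(0L, ends[-length(ends)])
  ann_idx <- findInterval(annotations$start, starts)
  sent_ann <- purrr::map(seq_along(starts), function(k) {
    sub <- annotations[ann_idx == k, , drop = FALSE]
    if (nrow(sub) == 0L) return(empty_annotations())
    annotation_tbl(sub$start - starts[k], sub$end - starts[k], sub$label, sub$surface)
  })
  tibble::tibble(
    doc_id = doc_id,
    sent_index = seq_along(starts) - 1L,
    text = slice_text(text, starts, ends),
    doc_offset = starts,
    annotations = sent_ann
  )
}

#' Rule-based sentence boundary detector
#'
#' Proposes a boundary after sentence-final punctuation (`.`, `!`, `?`)
#' followed by whitespace, and after blank lines; the trailing whitespace
#' is attached to the preceding sentence so boundaries tile the text.
#'
#' @param text A single string.
#' @return Integer vector of 0-based sentence end offsets; the last equals
#'   the text length.
#' @export
rule_splitter <- function(text) {
  n <- nchar_cp(text)
  m <- gregexpr("[.!?]+[\"')\\]]*[ \t]*(\n|$)|[.!?]+[\"')\\]]*[ \t]+|\n[ \t]*\n+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(n)
  ends <- as.integer(m) - 1L + attr(m, "match.length")
  ends <- sort(unique(c(ends[ends < n], n)))
  ends
}

#' Drop sentences without annotations
#'
#' Keeps only sentences carrying at least one annotation, preserving
#' order. The dropped count is reported via a message and attached as the
#' `dropped` attribute.
#'
#' @param sentences A sentence tibble.
#' @return The filtered sentence tibble.
#' @export
drop_unannotated <- function(sentences) {
  keep <- purrr::map_int(sentences$annotations, nrow) > 0L
  dropped <- sum(!keep)
  if (dropped > 0L) {
    rlang::inform(sprintf("drop_unannotated: removed %d of %d sentences",
                          dropped, length(keep)))
  }
  out <- sentences[keep, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}
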