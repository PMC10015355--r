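#' Build an annotation table
#'
#' Annotations are half-open character spans `[start, end)` over a text,
#' 0-based, counted in Unicode code points. `surface` is the text excerpt
#' covered by the span and must equal the slice of the owning text.
#'
#' @param start,end Integer vectors of span boundaries (0-based, half-open).
#' @param label Character vector of entity labels.
#' @param surface Character vector of covered text excerpts.
#' @return A tibble with columns `start`, `end`, `label`, `surface`,
#'   sorted by `start`.
#' @export
annotation_tbl <- function(start = integer(), end = integer(),
                           label = character(), surface = character()) {
  out <- tibble::tibble(
    start = as.integer(start),
    end = as.integer(end),
    label = as.character(label),
    surface = as.character(surface)
  )
  if (any(out$start < 0L) || any(out$end <= out$start)) {
    rlang::abort("annotation spans must satisfy 0 <= start < end")
  }
  dplyr::arrange(out, .data$start, .data$end)
}

empty_annotations <- function() annotation_tbl()

#' Build a document table
#'
#' A corpus is a tibble with one row per document: an identifier, the full
#' text, and a list-column of annotation tables (see [annotation_tbl()]).
#'
#' @param doc_id Character vector of document identifiers.
#' @param text Character vector of document texts.
#' @param annotations List of annotation tibbles, one per document.
#' @return A tibble with columns `doc_id`, `text`, `annotations`.
#' @export
document_tbl <- function(doc_id = character(), text = character(),
                         annotations = list()) {
  if (length(annotations) == 0L && length(doc_id) > 0L) {
    annotations <- replicate(length(doc_id), empty_annotations(), simplify = FALSE)
  }
  out <- tibble::tibble(
    doc_id = as.character(doc_id),
    text = as.character(text),
    annotations = annotations
  )
  purrr::pwalk(out, function(doc_id, text, annotations) {
    validate_annotations(annotations, text, doc_id)
  })
  out
}

# Spans must lie inside the text and surfaces must equal their slices.
validate_annotations <- function(ann, text, doc_id = "<doc>") {
  if (nrow(ann) == 0L) return(invisible(ann))
  n <- nchar_cp(text)
  if (any(ann$end > n)) {
    bad <- ann[ann$end > n, ][1, ]
    rlang::abort(sprintf(
      "annotation [%d, %d) in document '%s' extends past text length %d",
      bad$start, bad$end, doc_id, n
    ))
  }
  sl <- slice_text(text, ann$start, ann$end)
  if (any(sl != ann$surface)) {
    i <- which(sl != ann$surface)[1]
    rlang::abort(sprintf(
      "annotation surface mismatch in document '%s' at [%d, %d): '%s' vs slice '%s'",
      doc_id, ann$start[i], ann$end[i], ann$surface[i], sl[i]
    ))
  }
  invisible(ann)
}

# Code-point aware helpers; offsets are 0-based half-open throughout.
nchar_cp <- function(x) nchar(x, type = "chars")

slice_text <- function(text, start, end) {
  substring(text, start + 1L, end)
}

#' The closed label vocabulary of the medication-extraction tag set
#'
#' The nine labels of the n2c2 2018 Track 2 medication-extraction annotation
#' scheme. The corpus-synthesis default drops `Reason` and `ADE` before
#' projection, leaving the seven labels carried by the synthetic corpus.
#'
#' @param drop Labels to exclude (default none).
#' @return Character vector of labels.
#' @export
ner_labels <- function(drop = character()) {
  labs <- c("Drug", "Route", "Reason", "Strength", "Frequency",
            "Duration", "Form", "Dosage", "ADE")
  setdiff(labs, drop)
}

#' @rdname ner_labels
#' @export
projected_labels <- function() ner_labels(drop = c("Reason", "ADE"))
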