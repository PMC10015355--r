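#' Describe a de-identification placeholder dialect
#'
#' Placeholders are typed masks embedded in de-identified text, e.g. the
#' MIMIC-style `[**First Name**]`. The dialect is configurable: opening and
#' closing delimiters plus a keyword table mapping placeholder content to a
#' semantic mask type. Keywords are matched case-insensitively as
#' substrings of the placeholder content; unknown content is typed
#' `"other"`.
#'
#' @param open,close Delimiter strings.
#' @param type_map Named character vector: keyword -> mask type. Types are
#'   from `{name, date, year, phone, id_number, address, numeric, other}`.
#' @return A `mask_pattern` list.
#' @export
mask_pattern <- function(open = "[**", close = "**]",
                         type_map = default_mask_type_map()) {
  stopifnot(nzchar(open), nzchar(close))
  structure(list(open = open, close = close, type_map = type_map),
            class = "mask_pattern")
}

#' @rdname mask_pattern
#' @export
default_mask_type_map <- function() {
  c("name" = "name", "doctor" = "name", "patient" = "name",
    "date" = "date", "month" = "date", "day" = "date",
    "year" = "year",
    "phone" = "phone", "telephone" = "phone", "pager" = "phone",
    "number" = "id_number", "id" = "id_number", "mrn" = "id_number",
    "address" = "address", "hospital" = "address", "location" = "address",
    "numeric" = "numeric", "digits" = "numeric")
}

#' Detect typed de-identification masks in text
#'
#' Scans for delimiter-balanced placeholders and types each by the keyword
#' table of the pattern. Masks never overlap and are returned in document
#' order.
#'
#' @param text A single string.
#' @param pattern A [mask_pattern()].
#' @return A tibble with columns `start`, `end` (0-based half-open span of
#'   the whole placeholder including delimiters), `mask_type`, `content`.
#' @export
detect_masks <- function(text, pattern = mask_pattern()) {
  opens <- str_locate_all_fixed(text, pattern$open)
  closes <- str_locate_all_fixed(text, pattern$close)
  if (length(opens) == 0L && length(closes) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          mask_type = character(), content = character()))
  }
  starts <- integer(); ends <- integer(); contents <- character()
  ci <- 1L
  for (o in opens) {
    # next unconsumed close at or after the end of this opener
    while (ci <= length(closes) && closes[ci] < o + nchar_cp(pattern$open)) ci <- ci + 1L
    if (ci > length(closes)) {
      rlang::abort(sprintf("unbalanced mask delimiter opened at offset %d", o))
    }
    starts <- c(starts, o)
    ends <- c(ends, closes[ci] + nchar_cp(pattern$close))
    contents <- c(contents, slice_text(text, o + nchar_cp(pattern$open), closes[ci]))
    ci <- ci + 1L
  }
  if (ci <= length(closes)) {
    rlang::abort(sprintf("unbalanced mask delimiter closing at offset %d", closes[ci]))
  }
  tibble::tibble(
    start = starts, end = ends,
    mask_type = purrr::map_chr(contents, infer_mask_type, type_map = pattern$type_map),
    content = contents
  )
}

# 0-based start offsets of every occurrence of a fixed substring.
str_locate_all_fixed <- function(text, what) {
  m <- gregexpr(what, text, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m) - 1L
}

infer_mask_type <- function(content, type_map) {
  lc <- tolower(content)
  hit <- which(purrr::map_lgl(names(type_map), ~ grepl(.x, lc, fixed = TRUE)))
  if (length(hit)) unname(type_map[hit[1]]) else "other"
}

#' Replace masks with sampled surrogates, remapping annotation offsets
#'
#' Each mask is replaced by a surrogate of matching type drawn from the
#' sampler. Non-mask text is unchanged; every annotation disjoint from all
#' masks keeps its surface string; an annotation fully inside a mask is
#' retargeted to the whole surrogate span. An annotation straddling a mask
#' boundary is an error. Deterministic under a fixed seed.
#'
#' @param documents A document tibble.
#' @param samplers A named list of surrogate generators
#'   (see [builtin_samplers()]).
#' @param pattern A [mask_pattern()].
#' @return The document tibble with replaced text, remapped annotations,
#'   and two extra list-columns: `masks` (the detected masks with their
#'   surrogate) and `offset_map` (anchor pairs mapping old to new offsets,
#'   see [map_offset()]).
#' @export
replace_masks <- function(documents, samplers = builtin_samplers(1L),
                          pattern = mask_pattern()) {
  rows <- purrr::pmap(documents[, c("doc_id", "text", "annotations")],
                      replace_masks_one, samplers = samplers, pattern = pattern)
  dplyr::bind_rows(rows)
}

replace_masks_one <- function(doc_id, text, annotations, samplers, pattern) {
  masks <- detect_masks(text, pattern)
  ann <- annotations
  if (nrow(masks)) {
    straddle <- purrr::pmap_lgl(ann[, c("start", "end")], function(start, end) {
      any((start < masks$start & end > masks$start & end < masks$end) |
            (start > masks$start & start < masks$end & end > masks$end))
    })
    if (any(straddle)) {
      bad <- ann[straddle, ][1, ]
      rlang::abort(sprintf(
        "annotation [%d, %d) in document '%s' straddles a mask boundary",
        bad$start, bad$end, doc_id
      ))
    }
  }

  surrogate <- purrr::map2_chr(masks$mask_type, masks$end - masks$start,
                               function(type, width) draw_surrogate(samplers, type, width))
  masks$surrogate <- surrogate

  # rebuild text piecewise and record anchors (old, new) at segment starts
  pieces <- character(); old_anchor <- integer(); new_anchor <- integer()
  cursor_old <- 0L; cursor_new <- 0L
  for (k in seq_len(nrow(masks))) {
    keep <- slice_text(text, cursor_old, masks$start[k])
    old_anchor <- c(old_anchor, cursor_old); new_anchor <- c(new_anchor, cursor_new)
    pieces <- c(pieces, keep, surrogate[k])
    cursor_new <- cursor_new + nchar_cp(keep) + nchar_cp(surrogate[k])
    cursor_old <- masks$end[k]
  }
  old_anchor <- c(old_anchor, cursor_old); new_anchor <- c(new_anchor, cursor_new)
  pieces <- c(pieces, slice_text(text, cursor_old, nchar_cp(text)))
  new_text <- paste(pieces, collapse = "")

  omap <- tibble::tibble(old = c(old_anchor, nchar_cp(text)),
                         new = c(new_anchor, nchar_cp(new_text)))
  omap <- omap[!duplicated(omap$old), ]

  if (nrow(ann)) {
    new_span <- purrr::pmap(ann[, c("start", "end")], function(start, end) {
      remap_span(start, end, masks, omap)
    })
    ann <- annotation_tbl(
      start = purrr::map_int(new_span, 1),
      end = purrr::map_int(new_span, 2),
      label = ann$label,
      surface = slice_text(new_text,
                           purrr::map_int(new_span, 1),
                           purrr::map_int(new_span, 2))
    )
  }
  out <- document_tbl(doc_id, new_text, list(ann))
  out$masks <- list(masks)
  out$offset_map <- list(omap)
  out
}

draw_surrogate <- function(samplers, type, width) {
  gen <- samplers[[type]]
  if (is.null(gen)) {
    rlang::warn(sprintf("no sampler for mask type '%s'; using 'other'", type))
    gen <- samplers[["other"]]
  }
  gen(width)
}

# Map an annotation span through the mask replacements. Spans disjoint
# from every mask shift by the running length difference; spans fully
# inside a mask take the whole surrogate span.
remap_span <- function(start, end, masks, omap) {
  if (nrow(masks)) {
    inside <- which(start >= masks$start & end <= masks$end)
    if (length(inside)) {
      k <- inside[1]
      new_start <- map_offset(omap, masks$start[k])
      # surrogate occupies [new_start, next segment start)
      nxt <- omap$new[match(masks$end[k], omap$old)]
      return(c(new_start, nxt))
    }
  }
  c(map_offset(omap, start), map_offset_end(omap, end))
}

#' Map old-text offsets to new-text offsets
#'
#' The offset map is a tibble of strictly increasing `(old, new)` anchor
#' pairs recorded at the start of every unreplaced segment. Offsets inside
#' an unreplaced segment shift by the segment's anchor difference.
#'
#' @param omap Offset-map tibble with columns `old`, `new`.
#' @param pos Integer vector of old-text offsets.
#' @return Integer vector of new-text offsets.
#' @export
map_offset <- function(omap, pos) {
  idx <- findInterval(pos, omap$old)
  as.integer(omap$new[idx] + (pos - omap$old[idx]))
}

# End offsets are exclusive: map position - 1 then add 1, so a span ending
# exactly at a segment boundary stays inside its segment.
map_offset_end <- function(omap, pos) {
  map_offset(omap, pos - 1L) + 1L
}

#' Seeded surrogate generators per mask type
#'
#' Returns a named list of generator closures, one per mask type: `name`
#' (from a bundled first/last-name list), `date` (random day in one of the
#' configured formats), `year`, `phone`, `id_number`, `address`, `numeric`
#' (random digit string matching the mask width) and `other` (random
#' alphanumeric token). Each generator owns an independent RNG stream
#' derived from `seed`, so streams are reproducible and independent of the
#' global RNG state.
#'
#' @param seed Integer seed.
#' @param date_formats Candidate `strftime` formats for the date generator.
#' @return Named list of functions `f(width)` returning a single string.
#' @export
builtin_samplers <- function(seed, date_formats = c("%m/%d/%Y", "%Y-%m-%d", "%d %b %Y")) {
  first_names <- c("Alex", "Kim", "Jordan", "Maria", "Ahmed", "Li", "Sofia",
                   "Ivan", "Nora", "Paul", "Greta", "Hana", "Omar", "Jean")
  last_names <- c("Lee", "Smith", "Garcia", "Khan", "Novak", "Weber", "Rossi",
                  "Tanaka", "Brown", "Silva", "Kowalski", "Meyer", "Dubois")
  streets <- c("Main St", "Oak Ave", "Hill Rd", "Lake Dr", "Park Ln")

  stream <- function(offset) {
    env <- new.env(parent = emptyenv())
    env$state <- NULL
    function(f) {
      old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit({
        if (is.null(old)) {
          if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
      }, add = TRUE)
      if (is.null(env$state)) set.seed(seed + offset) else
        assign(".Random.seed", env$state, envir = globalenv())
      out <- f()
      env$state <- get(".Random.seed", envir = globalenv())
      out
    }
  }
  digits <- function(n) paste(sample(0:9, n, replace = TRUE), collapse = "")

  with_s <- list(
    name = stream(101L), date = stream(202L), year = stream(303L),
    phone = stream(404L), id_number = stream(505L), address = stream(606L),
    numeric = stream(707L), other = stream(808L)
  )
  list(
    name = function(width) with_s$name(function()
      paste(sample(first_names, 1), sample(last_names, 1))),
    date = function(width) with_s$date(function() {
      day <- as.Date("1990-01-01") + sample.int(12000L, 1L)
      format(day, sample(date_formats, 1))
    }),
    year = function(width) with_s$year(function()
      as.character(sample(1930:2020, 1))),
    phone = function(width) with_s$phone(function()
      sprintf("%s-%s-%s", digits(3), digits(3), digits(4))),
    id_number = function(width) with_s$id_number(function() digits(7)),
    address = function(width) with_s$address(function()
      paste(sample(10:999, 1), sample(streets, 1))),
    numeric = function(width) with_s$numeric(function() digits(max(1L, width))),
    other = function(width) with_s$other(function()
      paste(sample(c(letters, 0:9), max(3L, min(width, 12L)), replace = TRUE), collapse = ""))
  )
}
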