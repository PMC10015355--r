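# Registry of translation and alignment backends. Backends are plain
# functions registered under a name; external tools are wrapped by
# text-protocol adapters (bitext in, translations / Pharaoh links out).

the_backends <- new.env(parent = emptyenv())

#' Register or fetch translation / alignment backends
#'
#' A translator is `f(sentences, config)` returning one translated string
#' per input. An aligner is `f(pairs)` taking a tibble with columns
#' `source`, `target` and returning a list of link tibbles (`src`, `tgt`,
#' 0-based token indices).
#'
#' @param name Backend name.
#' @param fn Backend function.
#' @name backends
NULL

#' @rdname backends
#' @export
register_translator <- function(name, fn) {
  assign(paste0("tr_", name), fn, envir = the_backends)
  invisible(name)
}

#' @rdname backends
#' @export
register_aligner <- function(name, fn) {
  assign(paste0("al_", name), fn, envir = the_backends)
  invisible(name)
}

get_backend <- function(kind, name) {
  fn <- get0(paste0(kind, "_", name), envir = the_backends)
  if (is.null(fn)) {
    rlang::abort(sprintf("no %s backend registered under '%s'",
                         if (kind == "tr") "translator" else "aligner", name))
  }
  fn
}

#' Translation configuration
#'
#' @param backend_name Registered translator name.
#' @param beam_width Beam width passed through to the backend (default 5,
#'   the beam used for the neural machine translation step).
#' @return A `translation_config` list.
#' @export
translation_config <- function(backend_name = "identity", beam_width = 5L) {
  stopifnot(beam_width >= 1L)
  structure(list(backend_name = backend_name, beam_width = as.integer(beam_width)),
            class = "translation_config")
}

#' Translate sentences through a registered backend
#'
#' @param sentences Character vector of source sentences.
#' @param config A [translation_config()].
#' @return Character vector of translations, one per input, order kept.
#' @export
translate <- function(sentences, config = translation_config()) {
  if (length(sentences) == 0L) return(character())
  fn <- get_backend("tr", config$backend_name)
  out <- fn(sentences, config)
  if (length(out) != length(sentences)) {
    rlang::abort(sprintf("translator '%s' returned %d outputs for %d inputs",
                         config$backend_name, length(out), length(sentences)))
  }
  out
}

#' Word-align sentence pairs through a registered backend
#'
#' @param pairs Tibble with columns `source`, `target` (whitespace-tokenized
#'   sentences).
#' @param backend_name Registered aligner name.
#' @return List of link tibbles with 0-based columns `src`, `tgt`.
#' @export
align_pairs <- function(pairs, backend_name = "identity") {
  fn <- get_backend("al", backend_name)
  links <- fn(pairs)
  purrr::iwalk(links, function(l, i) {
    ns <- length(strsplit(pairs$source[i], "[ \t\n]+")[[1]])
    nt <- length(strsplit(pairs$target[i], "[ \t\n]+")[[1]])
    if (nrow(l) && (any(l$src < 0L | l$src >= ns) || any(l$tgt < 0L | l$tgt >= nt))) {
      rlang::abort(sprintf("aligner link out of token range in pair %d", i))
    }
  })
  links
}

#' Parse and format Pharaoh alignment records
#'
#' Pharaoh format encodes an alignment link set as space-separated `i-j`
#' tokens with 0-based source and target token indices.
#'
#' @param line A single Pharaoh record (may be empty).
#' @param pair_index Index reported in parse errors.
#' @return `parse_pharaoh()`: a tibble with columns `src`, `tgt`;
#'   `format_pharaoh()`: a single string.
#' @export
parse_pharaoh <- function(line, pair_index = NA_integer_) {
  line <- trimws(line)
  if (!nzchar(line)) return(tibble::tibble(src = integer(), tgt = integer()))
  toks <- strsplit(line, "[ \t]+")[[1]]
  ok <- grepl("^[0-9]+-[0-9]+$", toks)
  if (!all(ok)) {
    rlang::abort(sprintf("malformed Pharaoh token '%s' in pair %s",
                         toks[!ok][1], format(pair_index)))
  }
  parts <- strsplit(toks, "-", fixed = TRUE)
  tibble::tibble(src = as.integer(purrr::map_chr(parts, 1)),
                 tgt = as.integer(purrr::map_chr(parts, 2)))
}

#' @rdname parse_pharaoh
#' @param links Link tibble with columns `src`, `tgt`.
#' @export
format_pharaoh <- function(links) {
  paste(sprintf("%d-%d", links$src, links$tgt), collapse = " ")
}

#' Serialize sentence pairs as bitext
#'
#' One line per pair: source text, `" ||| "`, target text — the input
#' format consumed by statistical word aligners.
#'
#' @param pairs Tibble with columns `source`, `target`.
#' @return Bitext content as a single string.
#' @export
write_bitext <- function(pairs) {
  if (any(grepl("|||", pairs$source, fixed = TRUE) |
            grepl("|||", pairs$target, fixed = TRUE))) {
    rlang::abort("bitext separator '|||' may not occur inside a sentence")
  }
  if (any(!nzchar(trimws(pairs$target))) || any(!nzchar(trimws(pairs$source)))) {
    rlang::abort("bitext requires non-empty source and target sentences")
  }
  paste0(paste(pairs$source, "|||", pairs$target), collapse = "\n")
}

# --- built-in mock backends -------------------------------------------------

# Deterministic per-sentence permutation used by the reversible mock: a
# seeded choice of disjoint adjacent-pair swaps, derived from the sentence
# content so translate() and align() agree without shared state.
mock_permutation <- function(tokens, seed) {
  n <- length(tokens)
  if (n < 2L) return(seq_len(n))
  h <- sum(utf8ToInt(paste(tokens, collapse = " "))) %% 10000L
  perm <- seq_len(n)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed + h)
  swap <- stats::runif(floor(n / 2)) < 0.5
  for (k in which(swap)) {
    i <- 2L * k - 1L
    perm[c(i, i + 1L)] <- perm[c(i + 1L, i)]
  }
  perm
}

#' Built-in mock backends
#'
#' `identity`: the translation equals the source and links are `{(k, k)}`.
#' `reversible`: each token is suffixed with `_DE` and token order is
#' permuted by seeded adjacent-pair swaps; the aligner reconstructs exactly
#' the permutation used by the translator, so gold links are available by
#' construction. Both are registered at package load.
#'
#' @param seed Seed of the reversible mock's permutations.
#' @export
register_mock_backends <- function(seed = 42L) {
  register_translator("identity", function(sentences, config) sentences)
  register_aligner("identity", function(pairs) {
    purrr::map(seq_len(nrow(pairs)), function(i) {
      n <- length(strsplit(pairs$source[i], "[ \t\n]+")[[1]])
      m <- length(strsplit(pairs$target[i], "[ \t\n]+")[[1]])
      k <- seq_len(min(n, m)) - 1L
      tibble::tibble(src = k, tgt = k)
    })
  })
  register_translator("reversible", function(sentences, config) {
    purrr::map_chr(sentences, function(s) {
      toks <- tokenize_with_offsets(s)$token
      if (length(toks) == 0L) return(s)
      perm <- mock_permutation(toks, seed)
      paste(paste0(toks, "_DE")[perm], collapse = " ")
    })
  })
  register_aligner("reversible", function(pairs) {
    purrr::map(seq_len(nrow(pairs)), function(i) {
      toks <- tokenize_with_offsets(pairs$source[i])$token
      if (length(toks) == 0L) return(tibble::tibble(src = integer(), tgt = integer()))
      perm <- mock_permutation(toks, seed)
      # source token perm[j] sits at target position j
      tibble::tibble(src = perm - 1L, tgt = seq_along(perm) - 1L)
    })
  })
  invisible(c("identity", "reversible"))
}

#' External tool adapters
#'
#' Wrap a shell command as a backend over a pure text protocol: the
#' translator writes one sentence per line to a temporary file, runs
#' `cmd infile outfile`, and reads one translation per line; the aligner
#' writes bitext and reads Pharaoh records. No model is ever loaded in
#' process.
#'
#' @param cmd Path to the executable.
#' @param args Extra command-line arguments.
#' @return A backend function suitable for [register_translator()] /
#'   [register_aligner()].
#' @export
external_translator <- function(cmd, args = character()) {
  function(sentences, config) {
    fin <- tempfile("src_"); fout <- tempfile("tgt_")
    on.exit(unlink(c(fin, fout)), add = TRUE)
    writeLines(sentences, fin, useBytes = TRUE)
    status <- system2(cmd, c(args, "--beam", config$beam_width, fin, fout),
                      stdout = TRUE, stderr = TRUE)
    code <- attr(status, "status") %||% 0L
    if (code != 0L || !file.exists(fout)) {
      rlang::abort(sprintf("translator '%s' failed: %s", cmd,
                           paste(status, collapse = "\n")))
    }
    readLines(fout, warn = FALSE)
  }
}

#' @rdname external_translator
#' @export
external_aligner <- function(cmd, args = character()) {
  function(pairs) {
    fin <- tempfile("bitext_")
    on.exit(unlink(fin), add = TRUE)
    writeLines(write_bitext(pairs), fin, useBytes = TRUE)
    out <- system2(cmd, c(args, "-i", fin), stdout = TRUE, stderr = FALSE)
    code <- attr(out, "status") %||% 0L
    if (code != 0L) {
      rlang::abort(sprintf("aligner '%s' failed with status %d", cmd, code))
    }
    purrr::imap(out, parse_pharaoh)
  }
}

.onLoad <- function(libname, pkgname) {
  register_mock_backends()
}
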