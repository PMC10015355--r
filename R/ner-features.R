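# Token feature extraction and hashing for the Bloom-embedding stage.

#' Extract deterministic linguistic features from a token
#'
#' Four string features per token: lowercase form, 3-character prefix,
#' 3-character suffix, and a collapsed word shape (uppercase -> `X`,
#' lowercase -> `x`, digit -> `d`, runs capped at 4).
#'
#' @param token A single token string.
#' @return Named character vector `c(lower, prefix, suffix, shape)`.
#' @export
extract_features <- function(token) {
  lower <- tolower(token)
  n <- nchar_cp(token)
  c(lower = lower,
    prefix = substring(lower, 1L, min(3L, n)),
    suffix = substring(lower, max(1L, n - 2L), n),
    shape = word_shape(token))
}

word_shape <- function(token) {
  chars <- strsplit(token, "", fixed = TRUE)[[1]]
  mapped <- ifelse(grepl("[[:upper:]]", chars), "X",
                   ifelse(grepl("[[:lower:]]", chars), "x",
                          ifelse(grepl("[0-9]", chars), "d", chars)))
  out <- character(); run <- 0L; prev <- ""
  for (ch in mapped) {
    if (ch == prev) run <- run + 1L else { run <- 1L; prev <- ch }
    if (run <= 4L) out <- c(out, ch)
  }
  paste(out, collapse = "")
}

# Fixed polynomial rolling hash (Horner, base 31, modulus 2^31 - 1) with a
# per-feature-type salt. Stable across platforms; collisions are tolerated
# by design — that is the point of hashed (Bloom) embedding tables.
HASH_MOD <- 2147483647
FEATURE_SALTS <- c(lower = 17L, prefix = 8191L, suffix = 524287L, shape = 2654435L)

hash_feature <- function(value, salt, n_buckets) {
  h <- salt %% HASH_MOD
  for (code in utf8ToInt(value)) {
    h <- (h * 31 + code) %% HASH_MOD
  }
  as.integer(h %% n_buckets) + 1L
}

# n x 4 matrix of 1-based bucket indices for a token vector.
feature_buckets <- function(tokens, n_buckets) {
  t(vapply(tokens, function(tok) {
    f <- extract_features(tok)
    vapply(names(FEATURE_SALTS), function(k)
      hash_feature(f[[k]], FEATURE_SALTS[[k]], n_buckets), integer(1))
  }, integer(4)))
}
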