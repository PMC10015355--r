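# Stateful transition-based IOB parsing. The parser walks the sentence
# token-wise; the state at each position is (current token, first token of
# the last entity, previous token). Per-token feature-position vectors are
# precomputed by three dense layers (one per state slot); the state vector
# is their sum, passed through a hidden ReLU layer and a dense action
# scorer over {O} + {B-x, I-x}.

SENTINEL <- 0L

# Validity mask: I-x is only reachable right after B-x or I-x.
valid_actions <- function(actions, prev_action) {
  ok <- rep(TRUE, length(actions))
  is_inside <- startsWith(actions, "I-")
  if (is.na(prev_action) || prev_action == "O") {
    ok[is_inside] <- FALSE
  } else {
    prev_label <- substring(prev_action, 3)
    ok[is_inside & actions != paste0("I-", prev_label)] <- FALSE
  }
  ok
}

# Precompute the three feature-position matrices from encoded tokens.
position_vectors <- function(Enc, p) {
  list(cur = Enc %*% p$W_cur, last = Enc %*% p$W_last, prev = Enc %*% p$W_prev)
}

# One scoring step. Returns scores with invalid actions masked to -Inf.
score_state <- function(pos, t, last, prev, p, actions, prev_action) {
  s <- pos$cur[t, ]
  if (last != SENTINEL) s <- s + pos$last[last, ]
  if (prev != SENTINEL) s <- s + pos$prev[prev, ]
  s <- s + p$b_state
  hmask <- s > 0
  h <- s * hmask
  raw <- drop(h %*% p$W_out) + p$b_out
  masked <- raw
  masked[!valid_actions(actions, prev_action)] <- -Inf
  list(scores = masked, h = h, hmask = hmask)
}

advance_state <- function(action, t, last) {
  if (startsWith(action, "B-")) last <- t
  list(last = last, prev = t)
}

#' Parse a sentence into entity annotations
#'
#' Greedy stateful decoding: at each token the masked action scores are
#' computed and the argmax action taken; the emitted IOB2 tag sequence is
#' decoded to character spans through the token offsets. Masking
#' guarantees a valid non-overlapping span set even for an untrained
#' model.
#'
#' @param model A `ner_model`.
#' @param text Sentence text.
#' @return An annotation tibble (possibly empty).
#' @export
parse_sentence <- function(model, text) {
  toks <- tokenize_with_offsets(text)
  if (nrow(toks) == 0L) return(empty_annotations())
  tags <- predict_tags(model, toks$token)
  iob_to_spans(tags, toks, text)
}

#' @rdname parse_sentence
#' @param tokens Character vector of tokens (already tokenized).
#' @return `predict_tags()`: the IOB2 tag sequence.
#' @export
predict_tags <- function(model, tokens) {
  p <- model$params; cfg <- model$config
  emb <- embed_forward(tokens, p, cfg)
  enc <- encode_forward(emb$Y, p, cfg)
  pos <- position_vectors(enc$X, p)
  n <- length(tokens)
  tags <- character(n)
  last <- SENTINEL; prev <- SENTINEL; prev_action <- NA_character_
  for (t in seq_len(n)) {
    st <- score_state(pos, t, last, prev, p, model$actions, prev_action)
    a <- which.max(st$scores)
    tags[t] <- model$actions[a]
    upd <- advance_state(tags[t], t, last)
    last <- upd$last; prev <- upd$prev; prev_action <- tags[t]
  }
  tags
}

#' Annotate a sentence tibble with a trained model
#'
#' @param model A `ner_model`.
#' @param sentences A sentence tibble.
#' @return The tibble with a `predicted` list-column of annotation tibbles.
#' @export
annotate_sentences <- function(model, sentences) {
  dplyr::mutate(sentences,
                predicted = purrr::map(.data$text, ~ parse_sentence(model, .x)))
}
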