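# Training: teacher-forced cross-entropy over gold IOB2 action sequences,
# optimized by Adam with linear learning-rate decay; checkpoint selection
# by validation entity F1.

#' Training configuration
#'
#' @param lr Initial Adam learning rate (default 0.001).
#' @param adam_beta1,adam_beta2 Adam moment decay rates (defaults .9, .999).
#' @param max_steps Number of optimization steps; one step processes one
#'   sentence (default 2000).
#' @param eval_interval Validation-evaluation period in steps (default 200).
#' @param lr_decay_to Fraction of `lr` reached linearly at `max_steps`
#'   (default 0.1).
#' @param seed RNG seed for initialization and sentence order.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 0.001, adam_beta1 = 0.9, adam_beta2 = 0.999,
                         max_steps = 2000L, eval_interval = 200L,
                         lr_decay_to = 0.1, seed = 1L) {
  stopifnot(lr > 0, adam_beta1 > 0, adam_beta1 < 1,
            adam_beta2 > 0, adam_beta2 < 1, max_steps >= 1L)
  structure(list(lr = lr, adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 max_steps = as.integer(max_steps),
                 eval_interval = as.integer(eval_interval),
                 lr_decay_to = lr_decay_to, seed = as.integer(seed)),
            class = "train_config")
}

# Gold IOB2 action sequence for one sentence; errors if a span does not
# align with token boundaries.
gold_actions <- function(text, ann) {
  toks <- tokenize_with_offsets(text)
  spans_to_iob(ann, toks)
}

# Forward + backward over one teacher-forced sentence. Returns loss and
# the gradient list.
sentence_loss_grads <- function(tokens, tags, p, cfg, actions) {
  n <- length(tokens)
  emb <- embed_forward(tokens, p, cfg)
  enc <- encode_forward(emb$Y, p, cfg)
  pos <- position_vectors(enc$X, p)
  grads <- zero_grads(p)
  dPos <- list(cur = matrix(0, n, ncol(pos$cur)),
               last = matrix(0, n, ncol(pos$cur)),
               prev = matrix(0, n, ncol(pos$cur)))
  loss <- 0
  last <- SENTINEL; prev <- SENTINEL; prev_action <- NA_character_
  for (t in seq_len(n)) {
    st <- score_state(pos, t, last, prev, p, actions, prev_action)
    gold <- match(tags[t], actions)
    finite <- is.finite(st$scores)
    z <- st$scores[finite] - max(st$scores[finite])
    logZ <- log(sum(exp(z)))
    probs <- rep(0, length(actions))
    probs[finite] <- exp(z - logZ)
    loss <- loss - (st$scores[gold] - max(st$scores[finite]) - logZ)
    dscore <- probs; dscore[gold] <- dscore[gold] - 1
    grads$W_out <- grads$W_out + outer(st$h, dscore)
    grads$b_out <- grads$b_out + dscore
    ds <- drop(p$W_out %*% dscore) * st$hmask
    grads$b_state <- grads$b_state + ds
    dPos$cur[t, ] <- dPos$cur[t, ] + ds
    if (last != SENTINEL) dPos$last[last, ] <- dPos$last[last, ] + ds
    if (prev != SENTINEL) dPos$prev[prev, ] <- dPos$prev[prev, ] + ds
    upd <- advance_state(tags[t], t, last)
    last <- upd$last; prev <- upd$prev; prev_action <- tags[t]
  }
  grads$W_cur <- grads$W_cur + crossprod(enc$X, dPos$cur)
  grads$W_last <- grads$W_last + crossprod(enc$X, dPos$last)
  grads$W_prev <- grads$W_prev + crossprod(enc$X, dPos$prev)
  dEnc <- tcrossprod(dPos$cur, p$W_cur) + tcrossprod(dPos$last, p$W_last) +
    tcrossprod(dPos$prev, p$W_prev)
  eb <- encode_backward(dEnc, enc$caches, p, cfg, grads)
  grads <- embed_backward(eb$dX, emb, p, cfg, eb$grads)
  list(loss = loss / n, grads = grads)
}

adam_update <- function(p, grads, state, lr, b1, b2, step) {
  eps <- 1e-8
  for (nm in names(p)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^step)
    vhat <- state$v[[nm]] / (1 - b2^step)
    p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(p = p, state = state)
}

# Entity F1 of a model over a sentence tibble (exact-match, all labels).
model_entity_scores <- function(model, sentences) {
  pred <- purrr::imap(sentences$text, function(txt, i) {
    a <- parse_sentence(model, txt)
    a$sentence_id <- i
    a
  })
  gold <- purrr::imap(sentences$annotations, function(a, i) {
    a$sentence_id <- i
    a
  })
  rep <- entity_prf(dplyr::bind_rows(gold), dplyr::bind_rows(pred))
  tot <- rep[rep$tag == "Total", ]
  list(precision = tot$precision, recall = tot$recall, f1 = tot$f1)
}

#' Train the transition-based NER tagger
#'
#' Minimizes teacher-forced cross-entropy over gold IOB2 action sequences
#' with Adam (learning rate decayed linearly to `lr_decay_to` of its
#' initial value). Every `eval_interval` steps the model is evaluated on
#' the validation set by entity-level F1; the returned model is the
#' checkpoint with the highest validation F1, carrying the full training
#' curve as a tibble `(step, loss, precision, recall, f1)`.
#'
#' @param train_set,val_set Sentence tibbles with `text` and `annotations`.
#' @param model_cfg A [ner_config()].
#' @param cfg A [train_config()].
#' @return A trained `ner_model` with a `curve` tibble.
#' @export
ner_train <- function(train_set, val_set, model_cfg, cfg = train_config()) {
  if (nrow(train_set) == 0L) rlang::abort("empty training set")
  model <- ner_init(model_cfg, seed = cfg$seed)
  p <- model$params
  state <- list(m = zero_grads(p), v = zero_grads(p))
  examples <- purrr::map2(train_set$text, train_set$annotations, function(txt, ann) {
    toks <- tokenize_with_offsets(txt)
    list(tokens = toks$token, tags = spans_to_iob(ann, toks))
  })
  examples <- examples[purrr::map_int(examples, ~ length(.x$tokens)) > 0L]

  order_idx <- withr_seed(cfg$seed + 1L, {
    unlist(lapply(seq_len(ceiling(cfg$max_steps / length(examples))),
                  function(i) sample.int(length(examples))))
  })

  curve <- list(); best <- list(f1 = -1, params = p, step = 0L)
  running_loss <- 0; steps_since <- 0L
  for (step in seq_len(cfg$max_steps)) {
    ex <- examples[[order_idx[step]]]
    lr_t <- cfg$lr * (1 - (1 - cfg$lr_decay_to) * (step - 1L) / cfg$max_steps)
    lg <- sentence_loss_grads(ex$tokens, ex$tags, p, model$config, model$actions)
    upd <- adam_update(p, lg$grads, state, lr_t, cfg$adam_beta1, cfg$adam_beta2, step)
    p <- upd$p; state <- upd$state
    running_loss <- running_loss + lg$loss
    steps_since <- steps_since + 1L
    if (step %% cfg$eval_interval == 0L || step == cfg$max_steps) {
      model$params <- p
      sc <- model_entity_scores(model, val_set)
      curve[[length(curve) + 1L]] <- tibble::tibble(
        step = step, loss = running_loss / steps_since,
        precision = sc$precision, recall = sc$recall, f1 = sc$f1
      )
      running_loss <- 0; steps_since <- 0L
      if (sc$f1 > best$f1) best <- list(f1 = sc$f1, params = p, step = step)
    }
  }
  model$params <- best$params
  model$curve <- dplyr::bind_rows(curve)
  model$best_step <- best$step
  model$best_f1 <- best$f1
  model
}

#' Serialize / restore a model checkpoint
#'
#' The checkpoint is a single JSON document holding the configuration,
#' label set, and all parameter matrices (text, so it survives plain-text
#' transports).
#'
#' @param model A `ner_model`.
#' @param path File path.
#' @export
write_ner_model <- function(model, path) {
  payload <- list(
    config = unclass(model$config),
    actions = model$actions,
    params = lapply(model$params, function(x)
      if (is.matrix(x)) list(dim = dim(x), data = as.vector(x)) else list(dim = NULL, data = x))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ner_model
#' @export
read_ner_model <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- do.call(ner_config, payload$config[c("labels", "embed_width", "n_embed",
                                              "conv_depth", "conv_window",
                                              "hidden_width", "n_buckets")])
  params <- lapply(payload$params, function(x) {
    if (length(x$dim) == 2L) matrix(x$data, x$dim[[1]], x$dim[[2]])
    else as.numeric(x$data)
  })
  structure(list(params = params, config = cfg, actions = payload$actions,
                 curve = NULL),
            class = "ner_model")
}

#' @export
print.ner_model <- function(x, ...) {
  np <- sum(purrr::map_int(x$params, length))
  cat(sprintf("<ner_model> %d labels, %s parameters%s\n",
              length(x$config$labels), format(np, big.mark = ","),
              if (!is.null(x$best_f1)) sprintf(", best val F1 %.2f at step %d",
                                               x$best_f1, x$best_step) else " (untrained)"))
  invisible(x)
}
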