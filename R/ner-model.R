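# Model configuration, parameter initialization, and the forward passes of
# the embedding and convolutional encoding stages. All passes return the
# intermediates needed for the hand-written backward passes in ner-train.R.

#' NER model configuration
#'
#' The tagger has three stages: hashed (Bloom) feature embedding with
#' `n_embed` dense layers combined by elementwise max pooling and layer
#' normalization; a depth-`conv_depth` convolutional context encoder with
#' window `conv_window` and residual connections; and a stateful
#' transition parser scoring IOB actions from the sum of three
#' feature-position vectors (current token, first token of the last
#' entity, previous token). Default widths are kept small on purpose — the
#' architecture targets low computational requirements (megabyte-scale
#' models, CPU training in minutes).
#'
#' @param labels Entity label set.
#' @param embed_width Embedding width (default 96).
#' @param n_embed Number of dense embedding layers pooled by max (default 2).
#' @param conv_depth Number of convolution layers (default 4).
#' @param conv_window One-sided convolution window (default 1; the
#'   receptive field grows by `conv_window` tokens per layer).
#' @param hidden_width Parser hidden width (default 64).
#' @param n_buckets Rows of the hashed embedding table (default 2048).
#' @return A `ner_config` list.
#' @export
ner_config <- function(labels, embed_width = 96L, n_embed = 2L,
                       conv_depth = 4L, conv_window = 1L,
                       hidden_width = 64L, n_buckets = 2048L) {
  stopifnot(length(labels) >= 1L, embed_width > 0L, n_embed > 0L,
            conv_depth >= 0L, conv_window >= 1L, hidden_width > 0L,
            n_buckets > 1L)
  structure(list(labels = labels, embed_width = as.integer(embed_width),
                 n_embed = as.integer(n_embed), conv_depth = as.integer(conv_depth),
                 conv_window = as.integer(conv_window),
                 hidden_width = as.integer(hidden_width),
                 n_buckets = as.integer(n_buckets)),
            class = "ner_config")
}

# Action inventory: O first, then B-x / I-x per label.
action_set <- function(labels) {
  c("O", as.vector(rbind(paste0("B-", labels), paste0("I-", labels))))
}

glorot <- function(nr, nc) {
  matrix(stats::runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
}

#' Initialize an untrained NER model
#'
#' @param config A [ner_config()].
#' @param seed Integer seed for parameter initialization.
#' @return A `ner_model` list with `params`, `config`, `actions`.
#' @export
ner_init <- function(config, seed = 1L) {
  withr_seed(seed, {
    d <- config$embed_width; h <- config$hidden_width
    w <- config$conv_window
    actions <- action_set(config$labels)
    p <- list(E = glorot(config$n_buckets, d))
    for (i in seq_len(config$n_embed)) {
      p[[paste0("W_emb", i)]] <- glorot(4L * d, d)
      p[[paste0("b_emb", i)]] <- rep(0, d)
    }
    for (l in seq_len(config$conv_depth)) {
      p[[paste0("W_conv", l)]] <- glorot((2L * w + 1L) * d, d)
      p[[paste0("b_conv", l)]] <- rep(0, d)
    }
    p$W_cur <- glorot(d, h); p$W_last <- glorot(d, h); p$W_prev <- glorot(d, h)
    p$b_state <- rep(0, h)
    p$W_out <- glorot(h, length(actions))
    p$b_out <- rep(0, length(actions))
    structure(list(params = p, config = config, actions = actions, curve = NULL),
              class = "ner_model")
  })
}

# Evaluate expr under a temporary RNG state.
withr_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

LN_EPS <- 1e-8

#' Embed tokens through the hashed-feature Bloom embedding stage
#'
#' Each of the four token features is hashed into the shared embedding
#' table; the four feature vectors are concatenated and passed through
#' `n_embed` dense layers whose outputs are combined by elementwise max
#' pooling, then layer-normalized (so every output row has mean 0 and unit
#' variance up to `1e-8`).
#'
#' @param tokens Character vector of tokens.
#' @param model A `ner_model`.
#' @return Matrix of token vectors (`length(tokens)` x `embed_width`).
#'   Internally `embed_forward()` also returns the backward-pass cache.
#' @export
embed_tokens <- function(tokens, model) {
  embed_forward(tokens, model$params, model$config)$Y
}

embed_forward <- function(tokens, p, cfg) {
  n <- length(tokens); d <- cfg$embed_width
  buckets <- feature_buckets(tokens, cfg$n_buckets)
  # n x 4d concatenation of the four hashed feature vectors
  XC <- cbind(p$E[buckets[, 1], , drop = FALSE], p$E[buckets[, 2], , drop = FALSE],
              p$E[buckets[, 3], , drop = FALSE], p$E[buckets[, 4], , drop = FALSE])
  outs <- lapply(seq_len(cfg$n_embed), function(i)
    sweep(XC %*% p[[paste0("W_emb", i)]], 2, p[[paste0("b_emb", i)]], "+"))
  M <- outs[[1]]; argmax <- matrix(1L, n, d)
  if (cfg$n_embed > 1L) {
    for (i in 2:cfg$n_embed) {
      better <- outs[[i]] > M
      M[better] <- outs[[i]][better]
      argmax[better] <- i
    }
  }
  mu <- rowMeans(M)
  va <- rowMeans(M^2) - mu^2
  sd_ <- sqrt(va + LN_EPS)
  Y <- (M - mu) / sd_
  list(Y = Y, XC = XC, buckets = buckets, argmax = argmax, M = M,
       mu = mu, sd = sd_)
}

embed_backward <- function(dY, cache, p, cfg, grads) {
  d <- cfg$embed_width
  Yn <- cache$Y
  # layer norm backward (no affine parameters)
  dM <- (dY - rowMeans(dY) - Yn * rowMeans(dY * Yn)) / cache$sd
  dXC <- matrix(0, nrow(dM), 4L * d)
  for (i in seq_len(cfg$n_embed)) {
    mask <- cache$argmax == i
    dOi <- dM * mask
    Wn <- paste0("W_emb", i); bn <- paste0("b_emb", i)
    grads[[Wn]] <- grads[[Wn]] + crossprod(cache$XC, dOi)
    grads[[bn]] <- grads[[bn]] + colSums(dOi)
    dXC <- dXC + tcrossprod(dOi, p[[Wn]])
  }
  for (f in 1:4) {
    cols <- ((f - 1L) * d + 1L):(f * d)
    block <- dXC[, cols, drop = FALSE]
    for (r in seq_len(nrow(block))) {
      b <- cache$buckets[r, f]
      grads$E[b, ] <- grads$E[b, ] + block[r, ]
    }
  }
  grads
}

# Window concatenation: rows k-w .. k+w of X, zero-padded, as n x (2w+1)d.
conv_concat <- function(X, w) {
  n <- nrow(X); d <- ncol(X)
  out <- matrix(0, n, (2L * w + 1L) * d)
  for (o in -w:w) {
    cols <- ((o + w) * d + 1L):((o + w + 1L) * d)
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    out[ok, cols] <- X[src[ok], , drop = FALSE]
  }
  out
}

conv_scatter <- function(dC, w, d, n) {
  dX <- matrix(0, n, d)
  for (o in -w:w) {
    cols <- ((o + w) * d + 1L):((o + w + 1L) * d)
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    dX[src[ok], ] <- dX[src[ok], , drop = FALSE] + dC[ok, cols, drop = FALSE]
  }
  dX
}

#' Encode embedded tokens with the residual convolutional network
#'
#' Each layer concatenates a `2*conv_window + 1` row window, applies a
#' width-preserving dense projection with ReLU, and adds the input back
#' (residual). With `conv_depth = 0` the encoder is the identity.
#'
#' @param X Matrix of token vectors from [embed_tokens()].
#' @param model A `ner_model`.
#' @return Matrix of context vectors, same shape as `X`.
#' @export
encode_tokens <- function(X, model) {
  encode_forward(X, model$params, model$config)$X
}

encode_forward <- function(X, p, cfg) {
  caches <- vector("list", cfg$conv_depth)
  for (l in seq_len(cfg$conv_depth)) {
    C <- conv_concat(X, cfg$conv_window)
    Z <- sweep(C %*% p[[paste0("W_conv", l)]], 2, p[[paste0("b_conv", l)]], "+")
    H <- pmax(Z, 0)
    caches[[l]] <- list(C = C, mask = Z > 0)
    X <- X + H
  }
  list(X = X, caches = caches)
}

encode_backward <- function(dX, caches, p, cfg, grads) {
  d <- cfg$embed_width
  for (l in rev(seq_len(cfg$conv_depth))) {
    ca <- caches[[l]]
    dH <- dX * ca$mask
    Wn <- paste0("W_conv", l); bn <- paste0("b_conv", l)
    grads[[Wn]] <- grads[[Wn]] + crossprod(ca$C, dH)
    grads[[bn]] <- grads[[bn]] + colSums(dH)
    dC <- tcrossprod(dH, p[[Wn]])
    dX <- dX + conv_scatter(dC, cfg$conv_window, d, nrow(dX))
  }
  list(dX = dX, grads = grads)
}

zero_grads <- function(p) {
  lapply(p, function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x)))
}
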