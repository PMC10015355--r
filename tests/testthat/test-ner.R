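small_cfg <- function(labels = c("Drug", "Route")) {
  ner_config(labels, embed_width = 16L, n_embed = 2L, conv_depth = 2L,
             conv_window = 1L, hidden_width = 12L, n_buckets = 64L)
}

test_that("token features are deterministic and shape-collapsed", {
  f <- extract_features("Aspirin")
  expect_equal(unname(f["lower"]), "aspirin")
  expect_equal(unname(f["prefix"]), "asp")
  expect_equal(unname(f["suffix"]), "rin")
  expect_equal(unname(f["shape"]), "Xxxxx")
  expect_equal(unname(extract_features("81")["shape"]), "dd")
  expect_equal(extract_features("mg"), extract_features("mg"))
})

test_that("embedding rows are layer-normalized and token-deterministic", {
  model <- ner_init(small_cfg(), seed = 2)
  X <- embed_tokens(c("took", "aspirin", "took"), model)
  expect_equal(X[1, ], X[3, ])
  expect_true(all(abs(rowMeans(X)) < 1e-5))
  # lowercase feature differs across case variants, suffix bucket may agree
  b <- crossner:::feature_buckets(c("Aspirin", "aspirin"), 64L)
  expect_false(b[1, 1] == b[2, 1] && all(b[1, ] == b[2, ]))
  expect_equal(b[1, 3], b[2, 3])
})

test_that("encoder is the identity at depth 0 and local at depth d", {
  cfg0 <- ner_config(c("Drug"), embed_width = 16L, conv_depth = 0L,
                     n_buckets = 64L, hidden_width = 8L)
  m0 <- ner_init(cfg0, seed = 1)
  X <- embed_tokens(c("a", "b", "c"), m0)
  expect_equal(encode_tokens(X, m0), X)

  # receptive field: changing token k touches rows within k +- depth*window
  model <- ner_init(small_cfg(), seed = 5)
  toks1 <- c("t1", "t2", "t3", "t4", "t5", "t6", "t7", "t8", "t9")
  toks2 <- toks1
  toks2[5] <- "CHANGED"
  E1 <- encode_tokens(embed_tokens(toks1, model), model)
  E2 <- encode_tokens(embed_tokens(toks2, model), model)
  changed <- which(rowSums(abs(E1 - E2)) > 1e-12)
  expect_true(all(abs(changed - 5L) <= 2L))

  # constant input rows stay constant away from the zero-padded edges
  # (interior rows at depth*window tokens from either end share identical
  # receptive fields)
  Xc <- matrix(rep(X[1, ], 7), nrow = 7, byrow = TRUE)
  mnp <- ner_init(small_cfg(), seed = 3)
  Ec <- encode_tokens(Xc, mnp)
  expect_equal(Ec[3, ], Ec[4, ])
  expect_equal(Ec[4, ], Ec[5, ])
})

test_that("analytic gradients match numeric differentiation", {
  cfg <- ner_config(c("Drug"), embed_width = 6L, n_embed = 2L, conv_depth = 1L,
                    conv_window = 1L, hidden_width = 5L, n_buckets = 16L)
  model <- ner_init(cfg, seed = 3)
  tokens <- c("a", "bb", "ccc")
  tags <- c("O", "B-Drug", "I-Drug")
  slg <- crossner:::sentence_loss_grads(tokens, tags, model$params, cfg,
                                        model$actions)
  eps <- 1e-6
  set.seed(1)
  for (nm in names(model$params)) {
    x <- model$params[[nm]]
    for (i in sample(length(x), min(4, length(x)))) {
      p2 <- model$params
      p2[[nm]][i] <- p2[[nm]][i] + eps
      l1 <- crossner:::sentence_loss_grads(tokens, tags, p2, cfg, model$actions)$loss
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      l2 <- crossner:::sentence_loss_grads(tokens, tags, p2, cfg, model$actions)$loss
      expect_equal(slg$grads[[nm]][i] / length(tokens), (l1 - l2) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("untrained parse still emits a valid non-overlapping span set", {
  txt <- "Pt took aspirin 81 mg orally daily now ."
  valid_iob <- function(tags) {
    for (k in seq_along(tags)) {
      if (startsWith(tags[k], "I-") &&
          (k == 1L ||
             !tags[k - 1L] %in% paste0(c("B-", "I-"), substring(tags[k], 3)))) {
        return(FALSE)
      }
    }
    TRUE
  }
  for (seed in 1:10) {
    model <- ner_init(small_cfg(), seed = seed)
    ann <- parse_sentence(model, txt)
    expect_true(all(diff(c(0L, rbind(ann$start, ann$end))) >= 0))
    expect_true(all(ann$label %in% c("Drug", "Route")))
    expect_true(valid_iob(predict_tags(model, tokenize_with_offsets(txt)$token)))
  }
})

test_that("IOB decode inverts encode for token-aligned span sets", {
  sents <- fixture_sentences(seed = 3, n_documents = 5)
  for (i in seq_len(nrow(sents))) {
    toks <- tokenize_with_offsets(sents$text[i])
    tags <- crossner:::spans_to_iob(sents$annotations[[i]], toks)
    back <- crossner:::iob_to_spans(tags, toks, sents$text[i])
    expect_equal(back, sents$annotations[[i]])
  }
})

test_that("training descends, selects the best checkpoint, and is seeded", {
  train <- tagged_training_corpus(6L)
  cfg <- train_config(max_steps = 120L, eval_interval = 40L, seed = 8L)
  m1 <- ner_train(train, train, small_cfg(), cfg)
  m2 <- ner_train(train, train, small_cfg(), cfg)
  expect_equal(m1$curve, m2$curve)
  expect_lt(m1$curve$loss[nrow(m1$curve)], m1$curve$loss[1])
  expect_equal(m1$best_f1, max(m1$curve$f1))
  expect_error(ner_train(train[0, ], train, small_cfg(), cfg), "empty")
})

test_that("action-sequence decoding resolves B/I runs to character spans", {
  txt <- "took aspirin tablets now"
  toks <- tokenize_with_offsets(txt)
  ann <- crossner:::iob_to_spans(c("O", "B-Drug", "I-Drug", "O"), toks, txt)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$surface, "aspirin tablets")
  expect_equal(ann$label, "Drug")
})

test_that("model checkpoints round-trip through the JSON archive", {
  model <- ner_init(small_cfg(), seed = 4)
  path <- tempfile(fileext = ".json")
  write_ner_model(model, path)
  back <- read_ner_model(path)
  expect_equal(back$params, model$params)
  expect_equal(back$actions, model$actions)
  txt <- "Pt took aspirin orally ."
  expect_equal(parse_sentence(back, txt), parse_sentence(model, txt))
})
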