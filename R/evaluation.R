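# Evaluation: per-tag precision/recall/F1 with label-frequency-weighted
# totals, in three modes — exact-match entity spans, token-wise IOB tag
# assignment, and character-wise label classification.

new_eval_report <- function(per_tag, mode) {
  if (nrow(per_tag) == 0L) {
    per_tag <- tibble::tibble(tag = character(), precision = double(),
                              recall = double(), f1 = double(),
                              n_gold = integer())
  }
  tot <- weighted_total(per_tag)
  out <- dplyr::bind_rows(per_tag, tot)
  attr(out, "mode") <- mode
  class(out) <- c("eval_report", class(out))
  out
}

# Totals are gold-frequency-weighted means of the per-tag scores.
weighted_total <- function(per_tag) {
  if (nrow(per_tag) == 0L) {
    return(tibble::tibble(tag = "Total", precision = 0, recall = 0, f1 = 0,
                          n_gold = 0L))
  }
  w <- per_tag$n_gold
  if (sum(w) == 0) w <- rep(1, nrow(per_tag))
  tibble::tibble(
    tag = "Total",
    precision = stats::weighted.mean(per_tag$precision, w),
    recall = stats::weighted.mean(per_tag$recall, w),
    f1 = stats::weighted.mean(per_tag$f1, w),
    n_gold = sum(per_tag$n_gold)
  )
}

# Zero-denominator convention: a precision (recall) with no predicted
# (gold) items is 0, as is F1 when P + R = 0.
prf_row <- function(tag, tp, n_pred, n_gold) {
  p <- if (n_pred > 0) 100 * tp / n_pred else 0
  r <- if (n_gold > 0) 100 * tp / n_gold else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  tibble::tibble(tag = tag, precision = p, recall = r, f1 = f, n_gold = n_gold)
}

#' Entity-level precision, recall and F1 (exact span match)
#'
#' An entity counts as correct iff gold and prediction agree on sentence,
#' start, end and label (strict matching). Scores are percentages; the
#' `Total` row is the label-frequency-weighted mean with per-tag gold
#' counts as weights.
#'
#' @param gold,pred Span tibbles with columns `sentence_id`, `start`,
#'   `end`, `label` (extra columns ignored).
#' @return An `eval_report` tibble: `tag`, `precision`, `recall`, `f1`,
#'   `n_gold`, ending with the `Total` row.
#' @export
entity_prf <- function(gold, pred) {
  tags <- sort(unique(c(gold$label, pred$label)))
  key <- function(d) paste(d$sentence_id, d$start, d$end, d$label, sep = "\r")
  per_tag <- purrr::map(tags, function(tag) {
    g <- key(gold[gold$label == tag, , drop = FALSE])
    p <- key(pred[pred$label == tag, , drop = FALSE])
    tp <- multiset_intersection_size(g, p)
    prf_row(tag, tp, length(p), length(g))
  })
  new_eval_report(dplyr::bind_rows(per_tag), "entity")
}

multiset_intersection_size <- function(a, b) {
  ta <- table(a); tb <- table(b)
  common <- intersect(names(ta), names(tb))
  sum(pmin(ta[common], tb[common]))
}

#' Token-wise IOB evaluation
#'
#' Scores token-level tag assignments with `B-x` and `I-x` pooled per
#' label `x`: a token counts as a true positive for `x` when both gold and
#' predicted tags assign label `x` regardless of the B/I distinction.
#' Labels absent from both sides are omitted from the report.
#'
#' @param gold_tags,pred_tags Equal-length character vectors (or lists of
#'   per-sentence vectors) of IOB tags.
#' @return An `eval_report` tibble (mode `token_iob`).
#' @export
token_iob_eval <- function(gold_tags, pred_tags) {
  g <- unlist(gold_tags); p <- unlist(pred_tags)
  if (length(g) != length(p)) {
    rlang::abort(sprintf("tag sequences differ in length: %d vs %d",
                         length(g), length(p)))
  }
  strip <- function(x) ifelse(x == "O", "O", substring(x, 3))
  gl <- strip(g); pl <- strip(p)
  tags <- sort(setdiff(unique(c(gl, pl)), "O"))
  per_tag <- purrr::map(tags, function(tag) {
    prf_row(tag, sum(gl == tag & pl == tag), sum(pl == tag), sum(gl == tag))
  })
  new_eval_report(dplyr::bind_rows(per_tag), "token_iob")
}

#' Character-wise label classification F1
#'
#' Every character position carries at most one label per side; scores are
#' computed over the per-character label assignments, so they are
#' invariant to splitting a span into adjacent same-label spans.
#'
#' @param gold,pred Span tibbles with columns `sentence_id`, `start`,
#'   `end`, `label`.
#' @return An `eval_report` tibble (mode `char_label`).
#' @export
char_label_f1 <- function(gold, pred) {
  expand <- function(d, side) {
    if (nrow(d) == 0L) {
      return(tibble::tibble(pos = character(), label = character()))
    }
    out <- tidyr::unnest(
      dplyr::mutate(d, pos = purrr::map2(.data$start, .data$end,
                                         ~ seq(.x, .y - 1L))),
      "pos"
    )
    out <- dplyr::mutate(out, pos = paste(.data$sentence_id, .data$pos))
    if (anyDuplicated(out$pos)) {
      dup <- out[duplicated(out$pos) | duplicated(out$pos, fromLast = TRUE), ]
      if (length(unique(paste(dup$pos, dup$label))) > length(unique(dup$pos))) {
        rlang::abort(sprintf("overlapping %s spans with conflicting labels at %s",
                             side, dup$pos[1]))
      }
      out <- out[!duplicated(out$pos), ]
    }
    out[, c("pos", "label")]
  }
  g <- expand(gold, "gold"); p <- expand(pred, "pred")
  tags <- sort(unique(c(g$label, p$label)))
  per_tag <- purrr::map(tags, function(tag) {
    gp <- g$pos[g$label == tag]; pp <- p$pos[p$label == tag]
    prf_row(tag, length(intersect(gp, pp)), length(pp), length(gp))
  })
  new_eval_report(dplyr::bind_rows(per_tag), "char_label")
}

#' Seeded train/validation/test split
#'
#' Validation and test both get `round(ratio * n)` sentences; training
#' takes the remainder — with the canonical 80/10/10 ratios and n = 8599
#' this yields (6879, 860, 860). The shuffle is seeded and the partition
#' exact and disjoint.
#'
#' @param n_sentences Number of sentences.
#' @param ratios Train/validation/test fractions summing to 1.
#' @param seed Shuffle seed.
#' @return Named list of integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(n_sentences, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(n_sentences >= 3L, length(ratios) == 3L,
            abs(sum(ratios) - 1) < 1e-8)
  n_val <- max(1L, round(ratios[2] * n_sentences))
  n_test <- max(1L, round(ratios[3] * n_sentences))
  idx <- withr_seed(seed, sample.int(n_sentences))
  list(train = sort(idx[seq_len(n_sentences - n_val - n_test)]),
       val = sort(idx[seq(n_sentences - n_val - n_test + 1L, n_sentences - n_test)]),
       test = sort(idx[seq(n_sentences - n_test + 1L, n_sentences)]))
}

#' Corpus summary statistics
#'
#' @param sentences A sentence tibble.
#' @return A list with `n_sentences`, `n_tokens` (whitespace tokenizer),
#'   `per_label` (named counts), `n_annotations` (grand total).
#' @export
dataset_stats <- function(sentences) {
  labels <- unlist(purrr::map(sentences$annotations, "label"))
  per_label <- if (length(labels)) table(labels) else table(character())
  list(
    n_sentences = nrow(sentences),
    n_tokens = sum(purrr::map_int(sentences$text,
                                  ~ nrow(tokenize_with_offsets(.x)))),
    per_label = per_label,
    n_annotations = length(labels)
  )
}

#' Per-tag F1 differences between two evaluation reports
#'
#' @param report_a,report_b `eval_report` tibbles over the same label set
#'   (`a` is conventionally the model under study, `b` the baseline).
#' @return A tibble `tag`, `f1_a`, `f1_b`, `delta` (`f1_a - f1_b`),
#'   including the `Total` row.
#' @export
compare_models <- function(report_a, report_b) {
  if (!setequal(report_a$tag, report_b$tag)) {
    rlang::abort("compare_models requires identical label sets")
  }
  a <- tibble::tibble(tag = report_a$tag, f1_a = report_a$f1)
  b <- tibble::tibble(tag = report_b$tag, f1_b = report_b$f1)
  j <- dplyr::inner_join(a, b, by = "tag")
  dplyr::mutate(j, delta = .data$f1_a - .data$f1_b)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %s mode>\n", attr(x, "mode")))
  y <- as.data.frame(x)
  y$precision <- sprintf("%.2f", y$precision)
  y$recall <- sprintf("%.2f", y$recall)
  y$f1 <- sprintf("%.2f", y$f1)
  print(y, row.names = FALSE)
  invisible(x)
}
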