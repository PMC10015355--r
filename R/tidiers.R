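# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A tibble `tag`, `precision`, `recall`, `f1`, `n_gold`, `mode`,
#'   one row per tag plus the Total row.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x))
  out$mode <- attr(x, "mode")
  out
}

#' @rdname tidy.eval_report
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tot <- x[x$tag == "Total", ]
  tibble::tibble(precision = tot$precision, recall = tot$recall,
                 f1 = tot$f1, n_gold = tot$n_gold, mode = attr(x, "mode"))
}

#' Tidy a trained NER model's training curve
#'
#' @param x A `ner_model`.
#' @param ... Unused.
#' @return The curve tibble `(step, loss, precision, recall, f1)`.
#' @method tidy ner_model
#' @export
tidy.ner_model <- function(x, ...) {
  x$curve %||% tibble::tibble(step = integer(), loss = double(),
                              precision = double(), recall = double(),
                              f1 = double())
}

#' @rdname tidy.ner_model
#' @method glance ner_model
#' @export
glance.ner_model <- function(x, ...) {
  tibble::tibble(
    n_parameters = sum(purrr::map_int(x$params, length)),
    n_labels = length(x$config$labels),
    best_step = x$best_step %||% NA_integer_,
    best_val_f1 = x$best_f1 %||% NA_real_
  )
}

#' Tidy a corpus synthesis result
#'
#' @param x A `corpus_synthesis`.
#' @param ... Unused.
#' @return The per-pair bookkeeping tibble (`score`, `kept`, annotation
#'   counts).
#' @method tidy corpus_synthesis
#' @export
tidy.corpus_synthesis <- function(x, ...) x$pairs

#' @rdname tidy.corpus_synthesis
#' @method glance corpus_synthesis
#' @export
glance.corpus_synthesis <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    sentences_in = r$sentences_in, sentences_out = r$sentences_out,
    filtered = r$filtered,
    filter_rate = r$filtered / max(1L, r$sentences_in),
    annotations_in = r$annotations_in, annotations_out = r$annotations_out,
    threshold = r$threshold
  )
}

#' Plot a training curve
#'
#' Validation precision/recall/F1 against the training step.
#'
#' @param object A trained `ner_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ner_model
#' @export
autoplot.ner_model <- function(object, ...) {
  curve <- tidy(object)
  long <- tidyr::pivot_longer(curve, c("precision", "recall", "f1"),
                              names_to = "metric", values_to = "score")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$score,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "training step", y = "validation score (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a word-mapping matrix with its corner-to-corner diagonal
#'
#' @param m A binary alignment matrix.
#' @param ... Unused.
#' @return A ggplot object showing link cells and the reference diagonal
#'   used by the filter.
#' @export
plot_alignment_matrix <- function(m, ...) {
  nz <- which(m != 0, arr.ind = TRUE)
  cells <- tibble::tibble(src = nz[, 1], tgt = nz[, 2])
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$tgt, y = .data$src)) +
    ggplot2::geom_tile(fill = "grey30") +
    ggplot2::annotate("segment", x = 1, y = 1, xend = ncol(m), yend = nrow(m),
                      colour = "red", linetype = 2) +
    ggplot2::scale_y_reverse(breaks = seq_len(nrow(m))) +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(m)), position = "top") +
    ggplot2::labs(x = "target token", y = "source token") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot per-tag scores of an evaluation report
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot bar chart of per-tag F1 (Total drawn last).
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  d <- tidy(object)
  d$tag <- factor(d$tag, levels = c(setdiff(d$tag, "Total"), "Total"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tag, y = .data$f1)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "F1 (%)",
                  subtitle = sprintf("%s evaluation", attr(object, "mode"))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||% .data
NULL
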