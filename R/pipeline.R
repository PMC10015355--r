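# End-to-end pipeline wiring: standoff -> surrogate -> sentencize ->
# synthesize -> JSONL/CoNLL outputs, and split -> train -> evaluate.

#' Pipeline configuration with the canonical defaults
#'
#' Every field defaults to the reference settings of the synthesis recipe:
#' beam width 5, diagonality threshold 1.8, label blacklist Reason + ADE,
#' 80/10/10 split, Adam at lr 0.001 with betas .9/.999.
#'
#' @param translator,aligner Backend names.
#' @param beam_width Translation beam width.
#' @param t Diagonality filter threshold.
#' @param drop_labels Label blacklist applied before projection.
#' @param split_ratios Train/val/test fractions.
#' @param seed Master seed (surrogates, split, training).
#' @param mask_dialect A [mask_pattern()].
#' @param model_cfg,train_cfg Model / training configuration (built on
#'   demand from the projected label set when `NULL`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(translator = "identity", aligner = "identity",
                            beam_width = 5L, t = 1.8,
                            drop_labels = c("Reason", "ADE"),
                            split_ratios = c(0.8, 0.1, 0.1), seed = 1L,
                            mask_dialect = mask_pattern(),
                            model_cfg = NULL, train_cfg = NULL) {
  structure(list(translator = translator, aligner = aligner,
                 beam_width = as.integer(beam_width), t = t,
                 drop_labels = drop_labels, split_ratios = split_ratios,
                 seed = as.integer(seed), mask_dialect = mask_dialect,
                 model_cfg = model_cfg, train_cfg = train_cfg),
            class = "pipeline_config")
}

#' Run the corpus-synthesis pipeline
#'
#' Surrogate replacement, sentence splitting, removal of unannotated
#' sentences, then translation, alignment, diagonality filtering and
#' character-level annotation projection.
#'
#' @param documents A document tibble (e.g. from [read_standoff()] or
#'   [generate_masked_corpus()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, JSONL and CoNLL outputs,
#'   the synthesis report and a config snapshot are written there.
#' @return The `corpus_synthesis` object (see [synthesize_corpus()]) with
#'   an extra `stages` element recording per-stage sentence/annotation
#'   counts.
#' @export
run_synthesize <- function(documents, config = pipeline_config(), out_dir = NULL) {
  replaced <- replace_masks(documents, builtin_samplers(config$seed),
                            config$mask_dialect)
  sents <- split_sentences(replaced)
  n_split <- nrow(sents)
  sents <- drop_unannotated(sents)
  rlang::inform(sprintf("synthesize: %d documents -> %d sentences (%d annotated)",
                        nrow(documents), n_split, nrow(sents)))
  synth <- synthesize_corpus(sents, translator = config$translator,
                             aligner = config$aligner, t = config$t,
                             beam_width = config$beam_width,
                             drop_labels = config$drop_labels)
  synth$stages <- list(n_documents = nrow(documents), n_sentences_split = n_split,
                       n_sentences_annotated = nrow(sents))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out_docs <- dplyr::mutate(synth$sentences,
                              doc_id = paste0(.data$doc_id, "_s", .data$sent_index))
    writeLines(write_jsonl(document_tbl(out_docs$doc_id, out_docs$text,
                                        out_docs$annotations)),
               file.path(out_dir, "synthetic.jsonl"), useBytes = TRUE)
    writeLines(write_conll(synth$sentences), file.path(out_dir, "synthetic.conll"),
               useBytes = TRUE)
    jsonlite::write_json(synthesis_report_json(synth),
                         file.path(out_dir, "report.json"), auto_unbox = TRUE)
    write_config_snapshot(config, file.path(out_dir, "config.json"))
  }
  synth
}

synthesis_report_json <- function(synth) {
  r <- synth$report
  list(sentences_in = r$sentences_in, sentences_out = r$sentences_out,
       filtered = r$filtered, filter_rate = r$filtered / max(1L, r$sentences_in),
       annotations_in = r$annotations_in, annotations_out = r$annotations_out,
       discarded_by_label = as.list(r$discarded_by_label),
       threshold = r$threshold, translator = r$translator, aligner = r$aligner)
}

write_config_snapshot <- function(config, path) {
  snap <- config
  snap$mask_dialect <- list(open = config$mask_dialect$open,
                            close = config$mask_dialect$close,
                            type_map = as.list(config$mask_dialect$type_map))
  snap$model_cfg <- if (!is.null(config$model_cfg)) unclass(config$model_cfg)
  snap$train_cfg <- if (!is.null(config$train_cfg)) unclass(config$train_cfg)
  jsonlite::write_json(purrr::compact(unclass(snap)), path, auto_unbox = TRUE)
  invisible(path)
}

#' Split, train and evaluate on a synthesized corpus
#'
#' Splits the sentence tibble with [split_dataset()], trains the tagger,
#' and evaluates the selected checkpoint on the test split in token-wise
#' IOB and exact-match entity modes.
#'
#' @param sentences A sentence tibble with gold annotations.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for the training-curve CSV and
#'   report JSONs.
#' @return A list: `model`, `reports` (named `token_iob`, `entity`),
#'   `split` (the index lists), `curve`.
#' @export
run_train_eval <- function(sentences, config = pipeline_config(), out_dir = NULL) {
  labels <- sort(unique(unlist(purrr::map(sentences$annotations, "label"))))
  model_cfg <- config$model_cfg %||% ner_config(labels)
  train_cfg <- config$train_cfg %||% train_config(seed = config$seed)
  sp <- split_dataset(nrow(sentences), config$split_ratios, seed = config$seed)
  rlang::inform(sprintf("split: %d train / %d val / %d test",
                        length(sp$train), length(sp$val), length(sp$test)))
  model <- ner_train(sentences[sp$train, ], sentences[sp$val, ],
                     model_cfg, train_cfg)
  test <- sentences[sp$test, ]
  pred_ann <- purrr::imap(test$text, function(txt, i) {
    a <- parse_sentence(model, txt); a$sentence_id <- i; a
  })
  gold_ann <- purrr::imap(test$annotations, function(a, i) {
    a$sentence_id <- i; a
  })
  gold_tags <- purrr::map2(test$text, test$annotations, gold_actions)
  pred_tags <- purrr::map(test$text,
                          ~ predict_tags(model, tokenize_with_offsets(.x)$token))
  reports <- list(
    token_iob = token_iob_eval(gold_tags, pred_tags),
    entity = entity_prf(dplyr::bind_rows(gold_ann), dplyr::bind_rows(pred_ann))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(model$curve, file.path(out_dir, "training_curve.csv"),
                     row.names = FALSE)
    jsonlite::write_json(lapply(reports, as.data.frame),
                         file.path(out_dir, "reports.json"), auto_unbox = TRUE)
    write_config_snapshot(config, file.path(out_dir, "config.json"))
  }
  list(model = model, reports = reports, split = sp, curve = model$curve)
}
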