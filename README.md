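# crossner

Synthesis of annotated clinical NER corpora in a target language from
standoff-annotated source-language text, by machine translation, word
alignment, alignment-quality filtering and character-level annotation
projection — plus a lightweight trainable named-entity tagger and the
matching evaluation protocol.

## Who this is for

Clinical-NLP practitioners who have (or can license) an annotated English
corpus — the package speaks the n2c2/brat standoff dialect and the
medication label set Drug, Route, Reason, Strength, Frequency, Duration,
Form, Dosage, ADE — and want a corpus, and a baseline model, in another
language without collecting and annotating new clinical text. Everything is
driven through pluggable translator/aligner backends, so any MT system and
any word aligner that speak line-per-sentence and Pharaoh (`i-j`) text
protocols plug in; deterministic mock backends make the whole pipeline
testable without either.

## The method

1. **Surrogate replacement.** Typed de-identification masks (e.g.
   `[**First Name**]`) are replaced by sampled type-compatible surrogates;
   all annotation offsets are remapped through a strictly monotone offset
   map, and surfaces of annotations disjoint from masks are preserved
   exactly.
2. **Sentencize.** Documents are split into sentences (annotations carried
   over to sentence-relative offsets, boundary-straddling annotations force
   a merge) and unannotated sentences are dropped.
3. **Translate + align.** Sentences go through a translation backend (beam
   width b = 5 by default) and a word-alignment backend.
4. **Filter.** For each sentence pair the binary word-mapping matrix
   *A* (shape w_src × w_tgt) is scored by the mean perpendicular distance
   of its nonzero entries (i, j) to the diagonal line from (1, 1) to
   (w_src, w_tgt). Pairs whose score exceeds the threshold *t* (default
   1.8) are discarded — collapsed, scattered matrices are the signature of
   failed alignments.
5. **Project.** Each annotation's source tokens are followed through the
   link set; the projected span is the hull of the aligned target tokens,
   at character level. Unlinked spans are discarded with a logged reason;
   the labels Reason and ADE are blacklisted by default.
6. **Train + evaluate.** A small tagger (hashed Bloom feature embeddings →
   residual convolutional context encoder → stateful greedy transition
   parser over IOB2 actions) trains with Adam (lr 0.001, β₁ = .9,
   β₂ = .999); checkpoints are selected by validation F1 on an 80/10/10
   split. Reports cover exact-match entity, token-wise IOB, and
   character-wise label scoring, with label-frequency-weighted totals.

## Worked example

Everything below runs offline: the fixture generator builds a masked,
annotated corpus, and the `reversible` mock backend "translates" by
suffixing tokens with `_DE` and permuting them with a known alignment.

```r
library(crossner)

fx <- generate_masked_corpus(fixture_spec(seed = 42, n_documents = 8,
                                          mask_rate = 0.4))
substr(fx$documents$text[1], 1, 75)
#> [1] "Seen by [**First Name**] on admission. Pt took amoxicillin subcutaneously ."

synth <- run_synthesize(fx$documents,
                        pipeline_config(translator = "reversible",
                                        aligner = "reversible", seed = 42))
synth
#> <corpus_synthesis> 32/32 sentence pairs kept (t=1.80, 0 filtered)
#>   annotations: 145 in, 145 projected, 0 discarded (unlinked spans)

synth$sentences$annotations[[1]]
#> # A tibble: 2 × 4
#>   start   end label surface
#>   <int>   <int> <chr> <chr>
#> 1    14    28 Drug  amoxicillin_DE
#> 2    29    46 Route subcutaneously_DE
```

All 32 sentence pairs pass the filter (the mock's local reordering keeps
every link within one position of the diagonal) and all 145 annotations
project; the projected spans carry the translated surfaces at their new
character offsets. The filter itself is a two-liner to inspect:

```r
m <- alignment_matrix(tibble::tibble(src = c(0, 1, 2, 3),
                                     tgt = c(1, 0, 2, 3)), 4, 4)
diagonality_score(m)   # 0.3536 — one adjacent swap, well under t = 1.8
passes_filter(m, 1.8)  # TRUE
plot_alignment_matrix(m)
```

Training and evaluation chain off any annotated sentence tibble:

```r
sents <- drop_unannotated(split_sentences(fx$documents))
res <- run_train_eval(sents, pipeline_config(seed = 1))
res$reports$token_iob     # per-tag P/R/F1 (%), weighted Total row
autoplot(res$model)       # validation curve by training step
```

A thin command-line wrapper over these functions ships in
`inst/cli/crossner.R` (subcommands `synthesize`, `filter-stats`, `train`,
`evaluate`, `compare`, `fixtures`).

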