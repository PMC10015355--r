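---
title: "Synthesizing cross-lingual clinical NER corpora: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing cross-lingual clinical NER corpora: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossner)
```

## The problem

Open annotated corpora for clinical named-entity recognition exist almost
exclusively in English. For languages such as German, privacy law and
institutional policy have kept clinical text — and models trained on it —
unpublished. One way out is to *synthesize* a target-language corpus from a
public English one: translate the sentences with a neural machine
translation model, word-align each sentence pair, and project the
character-level entity annotations through the alignment onto the
translation. The result is a corpus whose provenance is entirely public, so
both the data recipe and any model trained on it can be released.

`crossner` implements that pipeline for medication-extraction annotations
(the n2c2 2018 Track 2 label scheme: Drug, Route, Reason, Strength,
Frequency, Duration, Form, Dosage, ADE), together with a lightweight
trainable NER tagger and the evaluation protocol used to measure the
synthesized corpus's usefulness. The access-restricted source corpus is
never bundled; a seeded synthetic-corpus generator produces structurally
equivalent fixtures so the whole pipeline is testable offline.

## Pipeline stages

### Surrogate replacement

De-identified clinical text carries typed placeholders (the default dialect
is the MIMIC-style `[**First Name**]`). Leaving them in place would bias
both translation and any downstream model, so each mask is replaced by a
sampled, type-compatible surrogate: names from a bundled name list, dates
formatted in common date formats, years, phone numbers, identifiers, and
digit strings matching the mask's width. Every replacement changes the
character geometry of the document, so all annotation offsets are remapped
through an anchor-based offset map. Three contracts are enforced and
tested: non-mask text is unchanged, every annotation disjoint from all
masks keeps its exact surface string, and the map is strictly
order-preserving. Annotations fully inside a mask are retargeted to the
whole surrogate span — the label still describes the replacement — and an
annotation straddling a mask boundary is an error rather than a silent
truncation. Surrogates are sampled independently per mask; document-level
consistency (the same patient name across masks) is deliberately not
attempted. Each sampler owns an independent seeded RNG stream, so surrogate
sequences are reproducible regardless of what else consumes the global RNG.

### Sentence splitting

Documents are split into sentences so that unannotated sentences can be
dropped before translation. The default splitter is rule-based
(sentence-final punctuation plus newline heuristics) and pluggable; the
downstream contracts do not depend on the splitter's identity. Sentence
spans tile the document text exactly, which makes reconstruction trivial
and keeps offset re-basing invertible. A proposed boundary that would cut
through an annotation is suppressed, merging the neighboring sentences:
merge-on-straddle guarantees annotation conservation, which truncation
would not.

### Translation and alignment backends

Translation and word alignment are pluggable contracts. External tools are
integrated strictly over text protocols — one sentence per line in, one
translation per line out; bitext (`src ||| tgt`) in, Pharaoh (`i-j`) link
records out — never by in-process model loading. Two deterministic mock
backends are first-class: `identity` (translation equals the source,
diagonal links) and `reversible` (tokens suffixed with `_DE`, order
permuted by seeded adjacent-pair swaps that the mock aligner reconstructs
exactly). The mocks make strong end-to-end properties testable: with the
identity backend the projected corpus must equal the source corpus
annotation-for-annotation; with the reversible backend gold alignments are
known by construction. The beam width of the translation step defaults
to 5.

### The diagonality filter

When a statistical aligner fails — typically on tabular or itemized text —
its word-mapping matrix collapses into a scattered, non-diagonal pattern.
The filter quantifies this: for the binary matrix $A$ of shape
$w_{src} \times w_{tgt}$, the score is the mean perpendicular Euclidean
distance of the nonzero entries $(i, j)$ (1-based) to the line through
$(1, 1)$ and $(w_{src}, w_{tgt})$. A pair is kept iff the score does not
exceed the threshold $t$, default $t = 1.8$. That default mirrors the
calibration procedure the recipe prescribes: plant a set of known
ill-aligned pairs and lower $t$ until all of them are detected. The test
suite re-enacts exactly that procedure with ten planted reversals.

Numerical choices worth recording:

* The score uses the canonical point-to-line distance (perpendicular
  Euclidean, computed via the cross product), which makes it transpose-
  symmetric. Distances are *not* normalized by sentence length; the
  threshold therefore implicitly scales with how far a link may stray in
  absolute token positions.
* A matrix with no links carries no usable alignment: it never passes,
  regardless of $t$.
* Degenerate $1 \times n$ matrices keep the line definition; for
  $1 \times 1$ the line collapses to the point $(1,1)$ and plain Euclidean
  distance is used (the only possible link then scores 0).

### Annotation projection

A source annotation is projected by collecting the source tokens its span
overlaps, following their alignment links, and taking the hull (minimum
start to maximum end) of the linked target tokens. Character-level target
spans must be contiguous, which is why the hull is used even when the
target tokens are not adjacent; with a permuting alignment this can pull
neighboring tokens into a span, a known and documented behavior rather
than a defect. If no token of the span carries a link the annotation is
discarded with a logged reason — that is the only discard mechanism. The
labels `Reason` and `ADE` are removed by a configurable blacklist before
projection; their definitions are too tied to the source corpus's
annotation context to survive transfer.

## The tagger

The bundled NER component is intentionally small — megabyte-scale
parameters, CPU training in minutes — because its role is to demonstrate
that the synthesized corpus carries learnable signal:

1. **Hashed (Bloom) feature embedding.** Four string features per token
   (lowercase form, 3-character prefix, 3-character suffix, collapsed word
   shape) are hashed into a shared 2048-row table with a fixed polynomial
   hash (base 31, modulus $2^{31}-1$, per-feature salt). Collisions are
   tolerated by design; that is what keeps the table small. The four
   feature vectors are concatenated, passed through `n_embed = 2` dense
   layers combined by elementwise max pooling, and layer-normalized
   (default width 96).
2. **Convolutional context encoding.** Four layers; each concatenates a
   three-token window, applies a width-preserving dense projection with
   ReLU, and adds a residual connection. The receptive field grows by one
   token per side per layer. Width-preserving projection was chosen where
   the architecture description leaves the dimension-constraining step
   ambiguous; it keeps the residual sum well-defined at every depth.
3. **Stateful transition parsing.** The parser walks the sentence greedily.
   Its state is three token indices: the current token, the first token of
   the last entity, and the previous token. Three per-slot dense layers
   precompute feature-position vectors for every token; the state vector is
   their sum, scored by a hidden ReLU layer and a dense layer over the
   actions {`O`} ∪ {`B-x`, `I-x`}. Invalid actions are masked (`I-x` only
   directly after `B-x`/`I-x`), so even an untrained model emits a valid
   non-overlapping span set.

Training minimizes teacher-forced cross-entropy over gold IOB2 action
sequences with Adam (learning rate 0.001, $\beta_1 = .9$,
$\beta_2 = .999$). "Decay" is implemented as a linear ramp of the learning
rate to 10% of its initial value over `max_steps`, exposed in
`train_config()` since the decay schedule is otherwise unspecified. The
model is evaluated on the validation set every 200 steps and the checkpoint
with the highest validation entity F1 is returned, along with the full
training curve. Gold sequences use IOB2 (every entity opens with `B-`);
parsing is greedy with no beam. All forward and backward passes are written
against base matrix operations and verified against numeric
differentiation in the test suite.

## Evaluation

Three scoring modes share one report shape (per-tag precision/recall/F1 in
percent plus a Total row):

* **entity**: exact span match (start, end, label all equal);
* **token_iob**: token-level tag assignment with `B-x`/`I-x` pooled per
  label;
* **char_label**: per-character label classification, invariant to
  splitting spans into adjacent same-label pieces.

Totals are label-frequency-weighted means using the gold counts of the
evaluated split. When recomputing published totals, note that printed
totals weight by the *test-split* frequencies, which published tables do
not list — so recomputing them from whole-corpus counts is not expected to
reproduce the printed numbers, and the package keeps printed totals as
given when building delta tables. Zero-denominator cases (no predictions,
or no gold) score 0 by convention. The 80/10/10 split assigns
`round(0.1 n)` sentences to validation and test each; at the reference
corpus size of 8599 sentences that is 6879/860/860.

## The synthetic-corpus generator

The generator emulates the *structure* of a masked clinical corpus:
templated medication sentences ("Pt took <Dosage> <Form> <Drug> <Strength>
<Route> <Frequency> <Duration> .") with entities from the 7-label set,
MIMIC-style typed masks inserted at a configurable rate (default 0.3), a
configurable fraction of unannotated filler sentences (default 0.3), and
deterministic pseudo-translations (token suffixing plus seeded local
reordering) with exact gold alignments. Scrambled pairs use full reversals
because a reversal's diagonality score grows linearly with sentence length
— about $n / (2\sqrt{2})$ for an $n$-token sentence — so any sentence of
nine or more tokens is guaranteed to exceed $t = 1.8$, making threshold
tests robust rather than tuned. Conversely, local adjacent-pair swaps move
no token more than one position, bounding each link's distance by
$1/\sqrt{2}$, so unscrambled pairs always pass.

What the generator does **not** emulate: real lexical variety, German
morphology, translation ambiguity, discontinuous entities in running text,
and the long tabular passages that defeat real aligners. Passing tests on
fixtures therefore demonstrate the *mechanics* — offset arithmetic,
conservation laws, filter behavior, trainability — not clinical-grade
accuracy on real data, which additionally requires the licensed source
corpus and a real translation model.

## Problem sizes and reproducibility

All randomness flows from explicit seeds: fixture specs, surrogate
samplers, the split, parameter initialization, and sentence order during
training. The test suite and the acceptance script use deliberately small
problem sizes chosen to exercise every code path while keeping runs quick:
500 random matrices up to 12×12 for the filter oracle, a 30-document
fixture for the calibration re-enactment, 1000 documents for surrogate
offset integrity, and a 10-sentence two-label corpus that the default
tagger memorizes to entity F1 100 well within 2000 steps. Reruns with the
same configuration are byte-identical, and every pipeline run can write a
JSON snapshot of its effective configuration.

## Known limitations

* The hull rule can widen projected spans under strongly permuting
  alignments; span-level precision on real parallel text will be bounded
  by alignment quality.
* The whitespace tokenizer is shared by the aligner interface, the CoNLL
  writer and the statistics; corpora with pathological whitespace should be
  normalized first.
* The tagger is a demonstration model: no pretrained embeddings, no
  transformer encoder, greedy decoding only.
* Offsets count Unicode code points. Sources that index by UTF-8 bytes
  must be converted before ingestion.
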