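---
title: "Collaborating single-task taggers for biomedical NER: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collaborating single-task taggers for biomedical NER: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collabotag)
```

## The problem

Biomedical NER gold standards are single-minded: a disease corpus annotates
diseases and nothing else, a gene corpus annotates genes. A tagger trained on
one of them never receives a labeled example saying "this token is an entity,
just not *your* kind of entity". The practical consequence is the *bio-entity
error*: polysemous names such as *VHL* (a disease in one sentence, a gene in
another) are tagged as the model's own type whenever they look entity-like,
because the evidence that would veto them lives in a different corpus.

`collabotag` implements the CollaboNet remedy: keep one single-task expert
per corpus, and during a phased schedule let each expert in turn train on its
own data *plus* the frozen encoder outputs of all the other experts, so that
"the gene expert already recognizes this token" becomes an input feature of
the disease expert.

## The single-task model

Each expert is a BiLSTM-CRF tagger over the BIOES scheme
(`n_tags = 4 * n_types + 1`, tag 1 is `O`).

**Embeddings.** A token `w_t` maps to the concatenation of a word-embedding
column `x_t` (dimension `d_word`, optionally initialized from a word2vec
text-format table; out-of-vocabulary tokens fall back verbatim → lowercased →
trainable UNK row) and a CNN character-level word embedding `x^c_t`: for each
odd window size `k`, every character position contributes a window vector
(the `k` character embeddings centred on it, PAD-embedded outside the word),
an affine filter bank maps each window to `d_clwe / n_windows` channels, and
a coordinate-wise maximum over positions pools them. The per-window-size
results are concatenated. A separate filter bank per window size (rather
than one merged bank) follows from the stated per-window output width.

**Encoder.** A standard LSTM per direction (input, forget, cell, output
gates; zero initial states), run over `[x̂_t ; s_t]` where `s_t` is the
*collaborator slot* — a fixed-width extra input (default `2 * d_lstm`) that
is all zeros when the model runs alone. Concatenating the slot at the
embedding-layer input (rather than deeper in the network) is the reading
most consistent with how a zero slot degrades exactly to the plain model.
Forward and backward states are concatenated to `h_t` of width `2 * d_lstm`.

**Emission and loss.** `z_t = W_y h_t + b_y` scores the tags. Training
minimizes the sum of two terms: the per-position softmax cross entropy, and
the CRF negative sentence-level log likelihood
`log Z - (A[start, y_1] + z_1[y_1] + Σ_t A[y_{t-1}, y_t] + z_t[y_t])`,
with the partition function computed by the forward algorithm in log space.
A `crf_loss = "neg_score"` switch drops the partition term, preserving the
literal "sum of transition and emission scores" variant for comparison; the
default keeps it, because only the normalized form is a log likelihood.

**Decoding.** Viterbi, with ties broken toward the lowest tag index at every
backtrack step so decoding is deterministic. The transition matrix is
learned freely — no `-Inf` masking of structurally invalid BIOES
transitions; instead a deterministic post-processing step
(`fix_invalid_bioes()`) repairs invalid output before span extraction:
orphan `I` at run start becomes `B`; an unclosed run ends in `E` (or `S` for
a singleton); orphan `E` becomes `S`; a type switch inside a run closes it.
The repair is total, idempotent, length-preserving and the identity on valid
sequences; the rules are this package's own choice, made to be local and
span-preserving.

## The collaboration protocol

*Preparation phase (P0).* Every expert trains independently (zero slot)
until its dev entity F1 fails to improve for `patience` (default 3)
consecutive epochs; the best-epoch checkpoint is kept. Dev F1 — not training
loss — defines convergence here, matching how the checkpoint is selected.

*Phases n ≥ 1.* For each dataset `d` in turn: every collaborator `k ≠ d`
encodes `d`'s sentences with its own slot zeroed and dropout disabled
(inference mode); the slot value is the coordinate-wise maximum over
collaborators of `α_k · h_k` ("weighted max pooling"; concatenation is a
config alternative). The target then trains for exactly one epoch on
`[x̂_t ; s_t]`. Collaborator parameters receive no gradient and are frozen
at the phase boundary for the whole phase, so within-phase dataset order
leaks no updates; the `α_k` (one scalar per target–collaborator pair,
initialized to 1) do receive gradient through the pooling. After all
datasets have been targets, the phase counter increments. By default the
target's embedding layers train along with the BiLSTM/CRF/α; a
`freeze_target_embeddings` flag restores the narrower reading that only the
encoder and CRF train. Phases run a fixed count, or until macro-average dev
F1 stagnates for `phase_patience` phases (mirroring the P0 rule, since no
stopping rule is otherwise fixed).

## Hyperparameters

| field | default | meaning |
|---|---|---|
| `d_word` | 200 | word-embedding dimension |
| `d_char` | 30 | character-embedding dimension |
| `windows` | 3, 5, 7 | char-CNN window sizes (odd) |
| `d_clwe` | 600 | total char-level word-embedding width (200 per window) |
| `d_lstm` | 300 | hidden units per LSTM direction |
| `dropout_clwe` | 0.5 | dropout on `x^c_t` before concatenation (training only) |
| `dropout_lstm` | 0.3 | dropout on the BiLSTM output (training only) |
| `lr`, `lr_decay` | 0.01, 0.95 | AdaGrad initial rate, per-epoch exponential decay |
| `batch_size` | 10 | sentences per mini-batch (gradients averaged) |
| `clip_norm` | 5.0 | global gradient-norm clip, guarding the finite-loss contract |

The `"desk"` profile (16/8/24 via a single window of 3, 32 hidden units) is
the same model at CPU scale; all synthetic-benchmark results in the tests
use it. Numerical choices: affine maps use uniform Glorot-style
initialization, character embeddings start uniform in
`[-0.5/d_char, 0.5/d_char]`, the transition matrix starts at zero;
initialization, shuffling and dropout all draw from R's RNG, so a single
`set.seed()` makes runs bit-reproducible. Pretrained word embeddings are
trainable by default (`freeze_word_embeddings` is available). A non-finite
training loss aborts with a diagnostic rather than continuing silently.

## The synthetic benchmark

`generate_corpora()` emulates the structural facts the protocol depends on,
over a shared vocabulary:

* one corpus per entity type, each tagging **only its own type** — mentions
  of other types occur but are `O`;
* unambiguous entity tokens carry a type suffix (`xqvw_gene`), learnable by
  the character CNN and invisible to a word-frequency baseline except
  through UNK handling;
* polysemous tokens (no suffix) are valid entities of any type; their gold
  type in a sentence is fixed by the nearest preceding cue token, and cue
  tokens occur nowhere else, so the annotation is a deterministic function
  of the token string;
* mentions are multi-token (2–3 tokens, `B/I*/E`) with probability 0.3,
  else single (`S`), so all five tags occur;
* consecutive mentions are separated by at least one filler token. Without
  this, adjacent entities make the segmentation irreducibly ambiguous
  (`B E | B I E` and `B I E | B E` read identically), capping exact-match F1
  below 1 for reasons that have nothing to do with the models;
* mentions take the corpus's own type with probability `own_type_rate`
  (default 0.8), mirroring how real single-type corpora are collected. This
  is what makes the planted difficulty real: each expert sees plenty of its
  own cue–polysemy associations and few of the others', so a lone model
  commits bio-entity errors that a collaborator can veto;
* sentence counts per split default to 2000/430/430 (roughly 70/15/15);
  mention counts per sentence are Poisson (`entity_rate`, capped at 3).

The fixed two-type benchmark (`polysemy_benchmark_spec()`: five polysemous
tokens, 800/200/200 sentences) is the configuration under which the test
suite and `scripts/acceptance.R` compare the phase-0 baseline with the
model after three collaboration phases. The sizes were chosen so that a full
preparation-plus-three-phases run takes well under a minute per seed on one
CPU while leaving each expert enough data to converge.

What the generator deliberately does **not** emulate: real token frequency
distributions (Zipf), abbreviation and orthographic phenomena, annotation
inconsistency between corpora, or document structure. Passing these
benchmarks therefore demonstrates that the implementation learns, that the
collaboration machinery transfers other-type evidence, and that the metrics
and error taxonomy behave as defined — not that any particular score would
be reached on real biomedical corpora.

## Evaluation

Scoring is exact-match at the entity level: a predicted span is correct only
if start, end and type all match a gold span (`P = C/M`, `R = C/N`,
`F1 = 2PR/(P+R)`; all three are 0 when their denominators vanish). Counts
are micro-averaged within a dataset; `macro_average()` takes the arithmetic
mean across datasets. Incorrect predictions are classified with precedence
*bio-entity* (matches or overlaps an other-type gold span; overlap is the
default because multi-word cases motivate it, with an exact-only flag) >
*span* (same-type overlap, wrong boundaries) > *spurious*; unmatched gold
spans are *missed*.

## Limitations

* The trainer is a single-threaded CPU implementation; it is meant for
  desk-scale experiments and protocol research, not for full-scale corpus
  training.
* One entity type per expert; joint multi-task training with shared
  parameters is out of scope.
* Tokenization and sentence splitting are assumed done upstream; corpora
  arrive in two-column CoNLL form.
* Checkpoints and state archives are RDS files written at run time; they are
  faithful but not a cross-language interchange format.
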