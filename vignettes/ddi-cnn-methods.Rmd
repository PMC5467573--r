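---
title: "Classifying drug-drug interactions with a one-layer CNN: model and design notes"
author: "ddicnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying drug-drug interactions with a one-layer CNN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddicnn)
```

## The problem

A drug-drug interaction (DDI) is an alteration of one drug's level or
activity caused by another drug. In the DDIExtraction 2013 task setting,
gold drug mentions are given and every pair of mentions in a sentence is a
*candidate instance* that must be classified into one of five classes:
*mechanism* (a pharmacokinetic interaction, e.g. altered clearance or
levels), *effect* (a pharmacodynamic consequence), *advice* (a
recommendation about co-administration), *int* (an interaction asserted
with no further detail) or *other* (no interaction). `ddicnn` implements a
single-hidden-layer convolutional neural network for this classification,
using only word and position embeddings as features — no syntactic parsing,
no hand-engineered feature sets — together with the preprocessing,
evaluation and experiment protocol around it, and a synthetic corpus
generator so the entire pipeline can be exercised and tested offline.

## Preprocessing

Each candidate pair becomes one instance:

1. **Discontinuous-mention filter.** Pairs in which either mention is
   discontinuous (a multi-range character offset, as in coordinated noun
   phrases like *"ganglionic or peripheral adrenergic blocking drugs"*)
   are removed and counted. Such mentions are a very small fraction of
   real corpora, and handling them is out of scope by design.
2. **Entity blinding.** The first mention of the pair is replaced (in the
   raw character stream, so multi-word names collapse to one token) by
   `drug1`, the second by `drug2`, and every other drug mention in the
   sentence by `drug0`. This forces the model to generalize across drug
   names. Overlapping bystander spans are resolved longest-first, and a
   bystander overlapping a pair mention is skipped; a pair whose two
   mentions overlap each other cannot be blinded and is dropped (counted).
3. **Tokenization.** Lower-casing plus an ordered, auditable list of
   regular-expression rules that put punctuation and special characters
   into their own tokens (`tokenizer_config()`); word-internal hyphens and
   digits are preserved so blinding labels survive intact. The rules are
   idempotent.
4. **Padding.** All instances share one length `n` (default 128),
   extended with the auxiliary token `"0"`. The default `n` is the
   corpus-maximum convention of the original study, so truncation never
   triggers there; on longer new data we truncate from the tail, and if
   that would lose either blinded entity we centre the window on the two
   entities instead. Instances whose entities cannot share any window are
   dropped and counted.

Pairs whose two mentions have identical surface text are kept by default
(`drop_identical_surface` enables the stricter convention used by some
related systems, for comparison).

## The model

Each token `i` of an instance is represented by the concatenation of its
word vector (row of `We`, dimension `me`) and two position vectors: rows
of `Wd1` and `Wd2` indexed by the shifted relative distances of token `i`
to the two blinded entities. The raw distance `i - p` in `(-n+1, n-1)` is
shifted affinely to `(1, 2n-1)` by `index = (i - p) + n`; padding tokens
are indexed by the same total formula. This yields the input matrix
`X` of shape `n x (me + 2 md)`; `md = 0` disables position features.

A bank of `m` filters per window size `w` (default `m = 200`,
`w in {3, 4, 5}`) produces score sequences

    s_i = g( sum_{j=1..w} < f_j , x_{i+j-1} > + b ),  i = 1 .. n-w+1

with `g = ReLU`. Max-over-time pooling keeps one value per filter; the
pooled vectors of all sizes are concatenated into `z`. At training time
`z` passes through dropout (`p = 0.5`); the result feeds a fully
connected softmax layer `o = z_d Ws + d` over the `k = 5` classes.

Training minimizes the summed cross entropy of the batch plus an l2
penalty on the softmax weights only,

    J(theta) = - sum_i log p(y_i | x_i, theta) + lambda ||Ws||^2 ,

by Adam over per-epoch reshuffled mini-batches (batch 50, 25 epochs).
The trainable set is `theta = (We, Wd1, Wd2, Ws with its bias, all
filters with their biases)` — embedding tables are fine-tuned, including
rows loaded from a pre-trained word2vec file.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n` | 128 | fixed instance length (tokens) |
| `me` | 300 | word-embedding dimension |
| `md` | 5 | position-embedding dimension; 0, 5 and 10 are the studied settings |
| `filter_sizes` | 3, 4, 5 | convolution window widths; 2, 4, 6 track the most common inter-entity distances |
| `m` | 200 | filters per window size |
| `dropout` | 0.5 | drop probability on the pooled vector |
| `l2` | 3 | coefficient of `||Ws||^2` added to the summed batch loss |
| `batch_size` | 50 | mini-batch size |
| `epochs` | 25 | training epochs (fixed-epoch protocol) |
| `lr`, `beta1`, `beta2`, `eps` | 1e-3, 0.9, 0.999, 1e-8 | Adam settings (not fixed by the original study) |

### Numerical and design choices

* **Loss sign.** The objective is the standard negative log-likelihood
  (the cross entropy to be minimized); probabilities are computed with a
  log-sum-exp guard.
* **l2 scope.** The penalty multiplies the squared Frobenius norm of
  `Ws` only, added once to each summed batch loss; biases are not
  penalized.
* **Dropout convention.** Inverted dropout: surviving units are scaled
  by `1/(1-p)` at training time, so evaluation applies no rescaling and
  simply omits the mask.
* **Initialization.** Embedding tables (`We`, `Wd1`, `Wd2`) are uniform
  on (-1, +1) — the stated random-initialization scheme for word vectors,
  extended to the position tables, which have no pre-trained source.
  Filters and `Ws` are uniform on (-0.1, +0.1); biases start at zero. A
  single seed fixes initialization, shuffling and dropout, so a run is
  bit-reproducible on one platform.
* **Ties.** `predict_cnn()` breaks probability ties toward the lowest
  class index, deterministically.
* **Implementation.** The convolution is evaluated as one dense matrix
  product per filter size against the stacked token matrix followed by
  shifted row-gathers (an im2col-free formulation); the max-pool backward
  pass is a single sparse scatter over the surviving windows. The
  backward pass is hand-derived and is checked against central
  differences in the test suite (worst relative error around 1e-6 in
  double precision at step 1e-5).
* **Degenerate inputs.** Empty training sets, empty score sequences,
  filters wider than `n`, and mismatched instance lengths are errors;
  instances the preprocessing cannot represent are dropped and counted,
  never silently mangled.

## Evaluation

Scoring follows the shared-task conventions. For each positive class,
`TP`, `FP` and `FN` are counted; a positive instance predicted as a
*different* positive class counts both as `FN` of its gold class and
`FP` of the predicted class, which makes the micro-averaged Overall row
the exact column sum of the class rows. `other` is excluded from
micro-averaging and never has its own row. `P = TP/(TP+FP)`,
`R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`, with zero-denominator conventions
`P = R = F1 = 0`. Metrics are returned unrounded (percentages); display
rounds to two decimals with R's `round()`, whose half-even behaviour
matches the reference tables (e.g. a recall of 27/96 = 28.125 displayed
as 28.12). Reports can be partitioned by document provenance
(drugbank-like vs medline-like subcorpora), and the partition counts add
exactly to the global counts.

Two models are compared by the 1-df chi-square statistic (no continuity
correction) on the 2x2 model-by-correctness table over all candidate
instances, computed via `stats::chisq.test()`; a difference is declared
significant iff the statistic strictly exceeds 3.84 *and* p < 0.05. The
contingency construction is our declared choice — the protocol names the
test and thresholds but not the table. Degenerate tables (identical
performance, or a zero margin) report a statistic of 0.

## The experiment harness

`split_train_validation()` holds out a target fraction (default 10%) of
instances *at the sentence level*, so no sentence contributes to both
sides; the split is deterministic under its seed and shared across the
configurations of a sweep for fairness. `run_sweep()` trains one model
per named configuration, scores validation (and optionally test — never
used for selection), computes the all-pairs chi-square matrix of the
validation predictions, and ranks by validation F1. The fixed-epoch
protocol (25 epochs, no early stopping) is the default; the per-epoch
learning curve (`learning_curve()`) reports the argmax-validation epoch
for inspection.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` emits corpora in the unified XML dialect whose
structure mirrors the real annotated corpus at desk scale:

* the positive-class mix defaults to the real corpus shares (advice
  20.9%, effect 41.1%, int 5.6%, mechanism 32.3% of positives); the
  non-interacting share defaults to 40% — the real corpus is far more
  imbalanced (about 85% negatives), but at a few hundred sentences that
  would leave single-digit counts for the rare classes, so we trade
  realism of the marginal for usable per-class counts and keep the
  proportions configurable;
* each positive class is signalled by a multi-token trigger phrase
  placed between the mentions when it fits (before them otherwise), so
  filter widths 2-6 can span it — mirroring the finding that the best
  filter sizes track the most common inter-entity distances;
* inter-entity token distances are drawn from a configurable
  distribution whose default has spikes at 2, 4 and 6 over a geometric
  tail to 40 (mean around 12-14), echoing the real distance profile;
* a configurable fraction of sentences (default 25%) carries a third
  bystander mention, exercising the `drug0` path and
  multiple-instances-per-sentence; label noise (default 5%) swaps the
  trigger phrase while keeping the label; documents are drawn roughly
  3:1 drugbank-like vs medline-like; a `discontinuous_rate` option
  produces a minimal coordinated-noun-phrase fixture for the drop
  filter.

What it deliberately does **not** emulate: real lexical variety (filler
tokens come from a closed ~30-word lexicon, so vocabularies stay
desk-scale), negation scope, anaphora, nested mentions, or the
pragmatics of real package-insert prose. Consequently, passing tests on
synthetic corpora demonstrate that the pipeline and optimizer behave as
specified — not that any particular F1 level transfers to real corpora;
corpus-level scores on the real data are explicitly out of reproduction
scope here because the corpus is an external download.

`generate_position_task()` builds a sharper diagnostic: the label
depends *only* on which band the inter-entity distance falls into. Every
sentence uses a single filler token, one shared length, and no trigger;
the trailing filler run always exceeds the widest filter so no window
can see both an entity and the sentence-final period (which would leak
the distance into the word channel — a subtlety we hit and fixed during
design). Class assignment is exactly balanced, making "a word-only model
performs at the class prior" a well-defined check. On this task a model
with `md = 10` separates the bands essentially perfectly, while the same
model with `md = 0` has provably identical pooled features for every
instance and collapses to a constant predictor at the 50% prior.

## Problem sizes used by the packaged checks

The test suite and the acceptance script run entirely on generated data,
sized for a single CPU: the overfit check trains the default model on
200 noise-free instances (training micro-F1 reaches 100%, mirroring the
near-100% training curve of the fixed-epoch protocol); the position
ablation uses 700 sentences split 50/50 at the sentence level; the
gradient check runs a miniature configuration (`n = 6, me = 4, md = 2,
w in {2, 3}, m = 3`) against central differences; the end-to-end
synthetic experiment trains on about 300 instances and scores a held-out
quarter. These sizes are the package's chosen study conditions and are
stated here so results are interpretable, not tuning knobs.

## Known limitations

* One hidden layer, single-channel embeddings, no attention or recurrent
  variants, and no two-step detect-then-classify pipeline — all
  deliberately outside scope.
* Word-vector *training* is not included; only loading word2vec text and
  binary files. Tokens missing from a loaded file (including the
  blinding labels) are randomly initialized and fine-tuned.
* The reader assumes gold entity mentions; entity recognition and
  relaxed-span matching are not implemented.
* Nested or overlapping mentions are preserved by the reader and
  resolved (or dropped, with counters) only at blinding time.
* Pure-R tensor math: fast enough for desk-scale studies (minutes per
  training run), not for corpus-scale sweeps.
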