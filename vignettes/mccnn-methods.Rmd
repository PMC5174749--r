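---
title: "Multichannel CNN relation extraction: model, preprocessing and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multichannel CNN relation extraction: model, preprocessing and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mccnn)
```

## The task

Biomedical relation extraction asks, for a pair of entity mentions in one
sentence, whether the sentence asserts a relation between them and of what
kind. The two canonical instances are drug-drug interaction (DDI)
extraction — a five-way decision among `advice`, `effect`, `mechanism`,
`int` and `negative` — and protein-protein interaction (PPI) extraction,
which is binary. A sentence with $n$ annotated mentions contributes
$\binom{n}{2}$ candidate pairs, most of them negative, so the raw task is
both imbalanced and noisy.

This package implements the whole pipeline around a multichannel
convolutional sentence classifier: corpus I/O in the standard XML dialects,
entity blinding, rule-based noise filtering, multichannel embedding lookup,
the CNN itself with from-scratch backpropagation, Adadelta training, and
micro-averaged evaluation. A synthetic-corpus generator makes every stage
testable end to end without external corpora.

## Preprocessing

**Tokenization.** Text splits on whitespace and punctuation boundaries;
punctuation marks become single-character tokens. Each annotated mention is
collapsed into a single token covering its whole span, so multiword drug
names ("hypotensive agents") behave as one word downstream. Token spans are
0-based inclusive character offsets and partition the non-whitespace text —
a property the test suite checks by reconstruction. How hyphens and slashes
inside *unannotated* text should tokenize is genuinely underdetermined; we
split at every punctuation boundary, which is the simplest rule consistent
with the collapsed-entity invariant.

**Blinding.** For a candidate pair, the earlier mention becomes `Entity1`,
the later `Entity2`, and every other mention `EntityOther`. The classifier
therefore generalizes over entity identities and sees only their positions
relative to the lexical context. Blinding preserves token count and is
independent of the label.

**Noise filters.** Two rules drop candidate pairs that almost never encode
an interaction:

* *Rule 1 (same name / abbreviation).* Removed if the two surfaces are
  equal after case-folding, if one is a parenthesized short form
  immediately following the other ("long form (SHORT)"), or if one is the
  initial-letter acronym of the other's words. No algorithm for
  "abbreviation of" is canonical; this three-clause predicate is a
  deliberate heuristic that covers the repeated-name case
  ("Anesthetics … anesthetics") and the two common abbreviation patterns.
* *Rule 2 (coordinate structure).* Removed if every token strictly between
  `Entity1` and `Entity2` belongs to `{",", "and", "or", EntityOther}` and
  at least one separator is present. Adjacent entities (nothing between)
  are not coordinate. The detector is token-set based by design: the
  pipeline uses no parser anywhere, and coordinate lists are resolvable
  lexically.

Filters apply to training and test data alike. For small PPI corpora the
recommended practice is to disable them (`apply_filters = FALSE`, or
`--no-filters` on the command line): on a few thousand instances the pairs
the rules would discard are worth more as training signal than the noise
they carry.

## The model

Let $D \in \mathbb{R}^{c \times v \times d}$ stack $c$ word-embedding
tables ("channels") over one vocabulary of size $v$, each $d$-dimensional.
A blinded token sequence of length $N$ maps to the multichannel input
$V \in \mathbb{R}^{c \times N \times d}$ by row lookup. For a filter
$W \in \mathbb{R}^{c \times h \times d}$ with bias $b$ and window size $h$,

$$m_k = f\Big(\sum_{i=1}^{c} V^i[k:k+h-1] \odot W^i + b\Big),
\qquad k = 1, \dots, N-h+1,$$

with $f$ the rectifier, giving the feature map
$C = [m_1, \dots, m_{N-h+1}]$. Max-over-time pooling keeps
$C^\* = \max C$; $M$ filters per window size and $K$ window sizes yield the
pooled feature vector $r \in \mathbb{R}^{KM}$ by concatenation in fixed
window order. Classification is a linear transform into confidence space,
$I = W_2 r$ with $W_2 \in \mathbb{R}^{O \times KM}$, followed by softmax
$s_j = e^{I_j} / \sum_k e^{I_k}$. Ties in the argmax break toward the
lowest class index, deterministically.

Notes on points the contract leaves open, decided here:

* **Bias** is per filter (the standard convention).
* **No softmax bias**: the output layer is exactly $I = W_2 r$.
* **Short sequences** are right-padded with `<PAD>` to the largest window
  size; within pooling, any window consisting purely of padding is masked
  to $-\infty$ so padding can never win the max. The `<PAD>` embedding row
  is frozen at zero and excluded from updates.
* **Out-of-table initialization**: vocabulary words absent from a
  pretrained channel — and the artificial symbols `Entity1`, `Entity2`,
  `EntityOther`, `<UNK>`, which are never looked up — draw i.i.d. uniform
  components in $[-0.25, 0.25]$, matching the scale of typical pretrained
  vectors.
* **All channels fine-tune independently** during training; the parameter
  set is $\theta = (D, W, W_2, b)$ in full.

## Training

Minibatch training minimizes the summed negative log-likelihood
$\mathrm{loss} = \sum_{i=1}^{L} -\log p(y_i \mid x_i)$ with Adadelta. A
final short batch is used as-is. Defaults (all overridable via
`train_config()`):

| parameter | default | note |
|---|---|---|
| filters per window $M$ | 200 | |
| window sizes $H$ | {6, 7, 8, 9} | {3, 4, 5, 6} suits shorter PPI sentences |
| minibatch $L$ | 20 | |
| epochs | 10 | fixed count, no early stopping |
| input noise | $\mathcal{N}(0.001,\ 0.001^2)$ | resampled per batch, never at prediction |
| max-norm on $W_2$ rows | 5 | applied after every update step |
| Adadelta $\rho$, $\epsilon$ | 0.95, $10^{-6}$ | the algorithm's canonical constants |

The Gaussian input-noise convention fixes only the mean at 0.001; the
standard deviation is unstated in the setup this follows, so we default it
to 0.001 as well (both configurable). Noise skips masked padding positions.
Gradients are hand-derived backpropagation through the pooling argmax and
the ReLU gate; their correctness is enforced by a central finite-difference
check over every parameter group at relative tolerance $10^{-4}$. With a
fixed seed the entire trajectory — shuffling, noise, updates — is
reproducible bit for bit, which the test suite verifies by checksum.

Window-size defaults deserve one caveat: published configurations for
DDI-length sentences vary between {6,7,8,9} and {5,6,7,8}; we default to
the former and leave the choice to `train_config(H = ...)`.

## Evaluation

Per-class precision/recall/F are one-vs-rest percentages. The **overall
micro-average pools TP/FP/FN across the positive classes only**, excluding
`negative` — the DDIExtraction 2013 convention; including the negative
majority class would make "overall" trivially high. Detection (DEC)
metrics collapse all positive classes into one `interaction` label before
scoring. Cross-validation (`cv_split()`) groups instances by source
sentence so near-duplicate pairs from one sentence never straddle a fold;
document-level grouping is a stricter community protocol that callers can
emulate by using document ids as sentence ids.

## The synthetic generator

`generate_corpus()` emulates the DDI annotation scheme with a known
decision structure: each normal sentence carries one target pair whose
class is encoded by a single cue token placed directly between the two
entities (negative targets get a filler token there); additional entities
and all remaining pairs are negative. Because the cue trigram
`Entity1 cue Entity2` is unique to the target pair, a Bayes-optimal
classifier reaches micro-F 100 on decoy-free corpora — so any shortfall is
attributable to the model or training, not the data. Decoy sentences
exercise the filters: repeated-name pairs (rule 1) and comma/"or"
coordinate lists (rule 2) at configurable rates, 0.1 each by default.
Fabricated channels cover configurable vocabulary fractions (1.0 and 0.7
by default, 16 dimensions) with class-clustered cue vectors, mimicking
partial-coverage pretrained tables.

What the generator does **not** emulate: real prose statistics, long-range
cue-entity dependencies, label noise, cue ambiguity, or sentence lengths
beyond ~20 tokens. Passing the learnability checks therefore demonstrates
that the pipeline and optimizer are correct, not that the architecture
reaches any particular accuracy on DDIExtraction 2013 or the PPI
benchmarks — those require the original corpora and large pretrained
embeddings.

## Problem sizes used by the checks

The learnability check trains on 2,000 decoy-free instances and evaluates
on 500 (five classes, two fabricated channels, $M = 32$, $H = \{3, 4\}$,
$L = 20$, 10 epochs) — large enough that convergence is unambiguous, small
enough to run routinely; the held-out micro-F it computes is the package's
headline self-check and must stay at or above 95. Gradient checks use a
deliberately tiny model ($v = 20$, $d = 6$, $c = 2$, $H = \{2, 3\}$,
$M = 3$, four classes) so finite differences stay well-conditioned.

## Known limitations

* Rule 1's abbreviation clause is a heuristic; acronyms with stop-words
  ("of", "the") skipped in the short form will be missed.
* Discontinuous entity spans keep only their first span (with a warning);
  sentences mixing discontinuous and overlapping annotations are rejected.
* Training is single-threaded R; at the published scale (hundreds of
  filters over tens of thousands of instances) a session takes hours, so
  full-benchmark replication is better scheduled than interactive.
* The checkpoint format stores full double precision JSON; files are
  portable but not compact.
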