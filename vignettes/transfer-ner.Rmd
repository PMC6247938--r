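---
title: "Silver-to-gold transfer learning for biomedical NER with a bi-LSTM-CRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Silver-to-gold transfer learning for biomedical NER with a bi-LSTM-CRF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Biomedical named entity recognition (BNER) locates mentions of genes,
proteins, diseases, chemicals or species in text. Hand-annotated
gold-standard corpora (GSCs) are reliable but small; silver-standard corpora
(SSCs), produced by harmonizing the output of several automatic taggers over
large document collections, are much larger but noisy: they miss true
mentions, annotate spurious generic spans (for example the bare words
"genes", "proteins" or "animals"), and get boundaries wrong. `bionertl`
implements the transfer-learning recipe that combines the two: train a
neural sequence tagger on the large noisy SSC first (the *source* phase),
then use its parameters to initialize training on the small clean GSC (the
*target* phase), and compare against a baseline trained on the GSC alone.

## The model

The tagger is a six-layer character+token bi-directional LSTM-CRF:

1. a **token embedding layer** (default 100 dimensions),
2. a **character embedding layer** (default 25 dimensions),
3. a **character bi-LSTM** (default 25 units per direction) whose final
   forward and backward states summarize each token's spelling,
4. a **token bi-LSTM** (default 100 units per direction) over the
   *character-enhanced token embeddings* — the concatenation of the token
   embedding and the character-level representation,
5. a **label prediction layer**: an affine map from the token bi-LSTM output
   to one score per label, and
6. a **label sequence optimization layer**: a linear-chain CRF over those
   emission scores with learned transition, start and end scores.

The LSTM cell is the coupled-gate peephole variant,

$$
\begin{aligned}
i_t &= \sigma(W_{xi} x_t + W_{hi} h_{t-1} + W_{ci} c_{t-1} + b_i)\\
c_t &= (1 - i_t) \odot c_{t-1} + i_t \odot \tanh(W_{xc} x_t + W_{hc} h_{t-1} + b_c)\\
o_t &= \sigma(W_{xo} x_t + W_{ho} h_{t-1} + W_{co} c_t + b_o)\\
h_t &= o_t \odot \tanh(c_t),
\end{aligned}
$$

i.e. there is no separate forget gate (the forget weight is $1 - i_t$), the
peephole terms are full matrix products rather than the diagonal peepholes
many libraries use, and the output gate reads the *current* cell state. The
package implements exactly this recurrence — `lstm_cell_step()` exposes a
single step, and the test-suite pins its scalar behaviour (for instance,
with all parameters zero and $c_{t-1} = 2$: $c_t = 1$,
$h_t = 0.5\tanh(1) \approx 0.380797$).

Emission scores are deliberately *unnormalized*: no per-token softmax is
applied, and all normalization happens globally in the CRF (the standard
LSTM-CRF formulation). `crf_log_partition()` computes the log partition
function by the forward algorithm in log space, `crf_neg_log_likelihood()`
the training loss, and `viterbi_decode()` the maximum-scoring label path
with ties broken toward the lowest label index. The exported R functions are
reference implementations written for clarity; training and batch
prediction run through a compiled C++ core, and the test-suite ties the two
routes together numerically (emission agreement to 1e-10, analytic
gradients against central finite differences of the R forward pass, CRF
quantities against exhaustive path enumeration on small instances).

## Training

Training follows per-example stochastic gradient descent: one clipped
update per sentence, no momentum and no minibatching. Two named
hyperparameter profiles capture the two phases:

| profile | learning rate | dropout | clip | patience |
|---|---|---|---|---|
| `source_profile()` | 0.0005 | 0.8 | 5.0 | 10 |
| `target_profile()` | 0.005  | 0.5 | 5.0 | 10 |

Dropout is the probability of *dropping* a unit of the character-enhanced
token embedding (inverted dropout, applied before the token bi-LSTM, only
during training). The aggressive source profile — slow learning rate, 80%
dropout — deliberately discourages convergence on the noisy source corpus
so that capacity remains for the target phase. Gradient clipping is by
global norm: if the gradient norm of a sentence exceeds 5.0, the whole
gradient is rescaled to norm 5.0.

Early stopping watches entity-level F1 on the development partition: after
10 consecutive epochs without improvement, training stops and the
parameters of the best dev-F1 epoch are returned. One refinement matters at
the corpus sizes this package targets: per-example SGD from a random
initialization spends its first epochs in an "all-O" regime in which the
tagger predicts no entities at all. The length of that phase is set by the
learning rate and the number of updates per epoch, not by model quality —
with hundreds of thousands of sentences per epoch it ends inside the first
epoch, while with a few thousand (or twenty) sentences it can span many
epochs. The patience counter therefore only starts once the model produces
its first entity prediction on the development set. This burn-in rule has
no tuned constant, and it leaves ordinary early-stopping behaviour
untouched (a dev-F1 trace of 50, 60, then ten flat epochs still stops at
epoch 12 and returns the epoch-2 parameters).

Reproducibility is strict: epoch `e` shuffles sentences and draws dropout
masks from a seed derived from `profile$seed` and `e`, so two runs with the
same configuration produce bit-identical checkpoints.

### Initialization

The design here was genuinely open (the choice is not dictated by the
method): embeddings are drawn uniformly on $\pm\sqrt{3/d}$ (unit row
variance), weight matrices are Glorot-uniform, and biases, CRF transitions
and boundary scores start at zero. Unknown tokens fall back from exact
match to lowercase match to a reserved UNK row; unseen characters map to an
UNK character.

## Transfer

`transfer_parameters()` initializes a target model from a source
checkpoint. The six parameter groups — `char_embedding`, `char_lstm`,
`token_embedding`, `token_lstm`, `projection`, `crf`, ordered lowest to
highest — can be transferred all together (the default) or as any subset,
which supports the classic "how many lower layers suffice?" experiment.
The target vocabulary is the union of the source vocabulary and the target
training vocabulary, so embedding rows learned on the large source corpus
are retained for words that the small target corpus never shows; rows for
genuinely new words keep their fresh seed-determined initialization. If the
label inventories differ, the projection and CRF groups are freshly
initialized (with a warning) rather than partially mapped. With identical
vocabularies and all layers transferred, the target model is
prediction-identical to the source model before any fine-tuning — an
invariant the test-suite asserts.

`run_transfer_experiment()` wires the two phases together: the silver
corpus (deduplicated against the gold document ids — a guard rejects any
overlap — and blacklist-filtered) is split 90/10 into train/dev for the
source phase, since the original experiments are silent on how source-phase
early stopping obtained its validation data; the gold corpus is split
60/10/30, and both arms are evaluated on the same held-out test partition.

## Evaluation

Scoring is entity-level and exact: a predicted mention counts only if its
document, character offsets and type all equal a gold mention. Precision,
recall and F1 are percentages, each defined as 0 when its denominator is 0
(the degenerate case is not specified by the metric's usual definition).
Macro averages across corpora are unweighted means of the per-corpus
metrics, not pooled counts. The headline statistic of a transfer experiment
is the *reduction in error*,
$(F1_{TL} - F1_{B})/(100 - F1_{B}) \times 100$ — the fraction of the
baseline's F1 shortfall that transfer eliminates.

`learning_curve()` subsamples the target train set at fractions of the
overall corpus size (a 10% fraction of a 100-document corpus trains on 10
documents), keeps dev and test fixed, and reports mean and sample standard
deviation (n−1 denominator, the right choice for n = 3 error bars) over
trials; the source model is trained once per trial and shared across
fractions. `error_overlap()` computes the TP/FP/FN intersection counts of
two systems for Venn-style comparison, and `paired_significance()`
implements a document-level approximate randomization test (9,999 shuffles
by default, exact enumeration available for tiny document sets). The
original experiments do not name their significance test; the
randomization test is this package's choice and is flagged as such in the
error-analysis output.

## The synthetic corpus generator

Because the real 23 GSCs and the CALBC silver corpus cannot be
redistributed, every part of the pipeline is exercised on generated
corpora that reproduce the *structure* of the problem:

- **Entity surfaces** are recombinations of morpheme pools (prefix + stem +
  suffix, e.g. "mapk" + "a" + "ase"), optionally followed by a head noun
  ("kinase", "receptor", "homolog") with probability 0.25. A 60-surface
  lexicon over a 100-document corpus guarantees that held-out splits
  contain surface forms never seen in training, so the character-level
  layers are genuinely exercised.
- **Context templates** place entities in sentences with stable lexical
  cues ("Expression of &lt;E&gt; was elevated …", "Mutations in &lt;E&gt;
  are associated with …"); 75% of sentences carry an entity. Distractor
  sentences contain generic plural terms ("proteins", "genes", "animals",
  "cells", "samples") that are never gold entities — exactly the surfaces
  that silver-corpus blacklist filtering targets.
- **Silver-corpus noise** is modeled directly at the annotation level:
  each gold annotation is dropped with probability `fn_rate` (default
  0.3), one boundary is moved by one token with probability
  `boundary_shift_rate` (default 0.05), and each distractor occurrence is
  spuriously annotated with probability `fp_rate` (default 0.1). This
  captures the property the method relies on — larger but noisier — with
  controllable rates, rather than simulating multiple taggers plus
  harmonization. Document text is never altered, and silver document ids
  are disjoint from gold ids for every seed.
- The default silver/gold size ratio is 10 (configurable); ratios of 100
  and more occur in practice, but 10 keeps the full experiment in minutes
  on one CPU.

What the generator does *not* emulate: the lexical diversity, ambiguity and
discourse structure of real abstracts, multi-class annotation, nested or
discontinuous mentions, and realistic tokenization pathologies. Passing
tests on generated corpora therefore demonstrate that the machinery is
correct and that the transfer effect appears under controlled noise; they
do not certify performance numbers on any real corpus.

## Numerical and procedural choices

- **Tokenization** (unspecified by the method): whitespace split, then
  leading/trailing punctuation split into separate tokens; hyphens and
  slashes stay inside tokens ("N-acetyl-cysteine" remains one token).
  Sentence boundaries are `[.!?]` + whitespace + uppercase, with a
  single-capital abbreviation guard ("A. thaliana"). Deterministic and
  dependency-free; real-corpus token counts from other tokenizers are not
  reproducible exactly, which is acceptable because all in-package counts
  use the same tokenizer.
- **Chunking scheme**: BIO (IOB2) by default, BIOES behind a flag. Label
  recovery applies the conlleval repair rule (an orphan `I-` opens a new
  entity), so scoring by character-offset mention sets is equivalent to
  conlleval phrase matching.
- **Overlapping annotations**: keep the longest, then the earliest; drop
  the rest with a warning. Discontinuous Brat spans are rejected with a
  warning. Annotations that straddle token boundaries snap outward to the
  minimal covering token span, and the snap count is recorded.
- **Split arithmetic**: train and dev sizes are floors of n×fraction; the
  remainder goes to test (60/10/30 on 100 documents; 6/1/3 on 10).
- **Viterbi ties** break toward the lowest label index at every
  backtracking step, making decoding fully deterministic.
- **Degenerate cases**: F1 is 0 when P + R = 0; the reduction in error is
  undefined (an error) at a perfect baseline; a single-trial learning
  curve reports SD 0.

## Problem sizes

The bundled experiment — also what `scripts/acceptance.R` reruns — uses a
100-document gold corpus (about 300 sentences), a 1000-document silver
corpus (about 3000 sentences) with default noise, model dimensions 25/10
(token/char embeddings) and 25/10 hidden units per direction, 3 trials,
and target-train fractions of 10% and 60%. This runs in roughly five
minutes on one CPU and reproduces the qualitative transfer effect: a large
F1 gap in favour of transfer at the 10% fraction, shrinking to nearly zero
at 60%. The memorization check (20 sentences, token-LSTM hidden size 8)
shows the capacity of the network but also a real limitation of
per-example SGD at the published target learning rate: with only 20
updates per epoch, the all-O regime alone consumes roughly the first 50
epochs, and reaching 100% training F1 takes on the order of 90+ epochs.
The package reports this honestly rather than inflating the learning
rate.

## Known limitations

- No minibatching, momentum, adaptive optimizers or learning-rate
  schedules — per-example SGD is the method's stated procedure.
- No GPU path; the compiled core is single-threaded C++.
- Brat support covers text-bound ("T") annotations only; relations,
  events, normalizations and attributes are ignored.
- Token-level or relaxed-overlap scoring modes are intentionally absent;
  scoring is exact-match only.
- Pretrained embeddings are accepted in word2vec text format and remain
  trainable, but no embedding model ships with the package; random
  initialization is the default.
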