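---
title: "Knowledge-base-reinforced relation extraction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-base-reinforced relation extraction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbrelex)
```

## The problem

Curated biological knowledge bases hold exactly the information a
relation extractor lacks when it reads a sentence in isolation: what a
gene or protein is called elsewhere, what it does, and what it reacts
with. kbrelex extracts gene/protein mentions and their directed
semantic relations (the eight-type family around protein–protein
interaction: `Interacts_With`, `Binds_To`, `Regulates_Expression`, ...)
from text in BioNLP-ST standoff format, and reinforces a BiLSTM
extractor with two kinds of curated knowledge:

* **annotation records** (UniProt-style): names, aliases, and functional
  text per entity, folded into the entity representation;
* **reaction models** (SBML, BioModels-style): species that
  co-participate in a curated reaction are treated as *related
  entities*, and their embedding vectors form an external memory that
  hidden states attend over.

## Model

For a sentence $X = (x_1, \dots, x_T)$, tokens are mapped to
200-dimensional word2vec-style embeddings $e_t$ and encoded by a
bidirectional LSTM into hidden states $h_t$ (forward and backward
states concatenated). For a candidate entity pair, the knowledge base
contributes a vector set $V = \{v_i\}$: the related entities of both
arguments, found by expanding each argument to all of its record names
and scanning every reaction of every curated model for
co-participation. Each name is embedded as the mean of its token
vectors.

Per time step, a learned bilinear form scores the relevance of each
memory vector to the current state,

$$\alpha_i \propto \exp\!\left(v_i^\top U_v\, h_t\right), \qquad
  s_t = \sum_{i \in V} \alpha_i v_i, \qquad
  h_t' = h_t + P\, s_t,$$

with the softmax computed after subtracting the maximum logit. When $V$
is empty — the entity is unknown to the knowledge base — $s_t = 0$ and
$h_t' = h_t$ exactly, so the model degrades gracefully to a plain
BiLSTM. Because the hidden state has $2 \times 200 = 400$ components
while $v_i$ has 200, the summary is bridged by a learned projection $P$
initialized as stacked scaled identity blocks, so fusion starts out as
near-plain addition; when the dimensions agree no projection is needed.

The fused states are pooled into a sentence vector by word-level
attention with a learned context vector $u$ (weights
$\propto \exp(u^\top \tanh h_t')$), and a softmax layer predicts the
label, $p_y = \mathrm{softmax}(W h')$, $y' = \arg\max_y p_y$, with ties
broken toward the lowest label index. Unannotated candidate pairs carry
the null label `NONE`, which is excluded from micro-averaged
precision/recall/F1, following shared-task convention.

**Entity extraction** is two-staged. Stage 1 tags token positions with
the four-tag BIOE alphabet (Begin/Inside/Outside/End) using the same
encoder — per-token KB attention included when enabled — with either
independent softmaxes or a linear-chain CRF (learned 4×4 transitions
plus boundary scores; exact Viterbi decoding). Stage 2 types each
decoded span from its entity representation: the mean of the surface's
token vectors plus the summed annotation vector of its records, fused
with attention over the span's own related entities.

## Interpretation choices the source description leaves open

* **State size**: "state size 200" is read as 200 *per direction*, so
  $h_t$ has 400 components and $U_v$ is $200 \times 400$. The
  alternative (100 + 100) would halve capacity for no gain in clarity.
* **Aggregation**: annotation text is a bag of evidence, so annotation
  vectors are *sums* of token vectors; entity surfaces and related
  entity names are *means*, which keeps them scale-invariant in name
  length. Where several records match one surface it is undecidable
  which is right, so all are combined.
* **Reaction participants** are reactants ∪ products ∪ modifiers:
  catalysts and regulators interact with a reaction's substrates even
  though they are not consumed, and including them maximizes recall of
  interacting species.
* **Name matching** is exact after normalization (case-fold, trim,
  collapse internal whitespace). No stemming or fuzzy matching: every
  retrieval hit is auditable.
* **Singleton entities** are tagged bare `B` (begin with implicit end),
  keeping the four-tag alphabet closed; the decoder treats a `B` not
  followed by `I`/`E` as a closed singleton. Invalid model output is
  repaired, never rejected: `I`/`E` without a preceding `B` opens a
  span, an unclosed run closes at its last token.
* **Sentence-level pooling** uses attentive pooling with a learned
  context vector rather than max/mean, consistent with the
  attention-based BiLSTM family this model extends.
* **Pair-level memory**: one attention memory per candidate pair — the
  deduplicated union of both arguments' related entities — rather than
  per-argument memories, so a single attention distribution weighs all
  external evidence for the pair.
* **Candidate pairs** are all ordered co-sentential pairs; relations
  are directed (`arg1` → `arg2`) and evaluation requires an exact
  (type, arg1, arg2) match. Cross-sentence relations are out of scope
  (long multi-sentence inputs are a known failure mode of
  sentence-level encoders).

## Training

AdaDelta (decay 0.95, stabilizer $10^{-6}$) with learning-rate
multiplier 1.0 (0.8/0.9 admitted), per-minibatch L2 strength
$10^{-5}$, minibatch 10 (20 for large corpora), dropout 0.3 on the
recurrent layer's inputs during training only. Word embeddings are a
fixed input, not a trained parameter. Every candidate pair without a
gold relation becomes a `NONE` training instance; a flag can cap the
negative:positive ratio, but by default nothing is subsampled. Early
stopping, when a validation fraction is held out, monitors validation
micro-F1 with patience 10; neither an epoch budget nor a stopping rule
is inherent to the model, so these are package defaults. Training is
deterministic on CPU for a fixed seed; shuffling is seeded after
parameter initialization so that a KB-attentive model whose memory is
always empty follows the exact trajectory of the no-KB model.

Gradients for the whole network — BPTT through both LSTM directions
(compiled code), the bilinear attention, the pooling layer, the softmax
heads, and the CRF (forward–backward marginals) — are hand-derived and
verified against central finite differences in the test suite.

Out-of-vocabulary tokens get deterministic pseudo-random vectors,
Uniform(−0.25, 0.25) per component (a standard embedding-initialization
scale), seeded per token so repeated runs agree; the draw is isolated
from the global RNG stream.

## What the synthetic generator emulates — and what it does not

The fixture generator emulates the *structure* of the study data
without any download: standoff-annotated documents with typed
single-token Gene/Protein mentions, annotation records with multi-name
alias sets, and curated reaction models whose co-participation is
predictive of relation labels. Two independent evidence channels
connect a pair to its label:

* a **lexical trigger** token between the entities (probability
  `p_trigger`);
* a **reaction** containing both surfaces plus a label-specific marker
  species (probability `kb_signal`).

Because the channels are independent, ablations attribute performance
causally: with `p_trigger = 0` the knowledge pathway is the *only*
signal. Entity surfaces for gold pairs are freshly generated per pair,
so surface identity cannot leak labels across a train/test split;
negative sentences reuse a small shared pool. Defaults mirror the
observed coverage of the reference knowledge bases — records for ~75%
of entity surfaces, reactions behind ~54% of gold pairs — and planted
relations are annotated in both directions by default, since the PPI
relation family is predominantly symmetric.

What the generator does **not** emulate: real biomedical language
(sentences are template token streams), multi-token and discontinuous
mentions in running text, class imbalance of real shared-task data,
noisy or partial KB name overlap (synthetic names match records
exactly), and cross-sentence phenomena. Passing the planted-signal
tests therefore demonstrates that the KB-attention pathway works as a
mechanism — it retrieves, weighs, and exploits external evidence — not
that any particular benchmark score would be reached on real corpora,
which require the original shared-task downloads and live knowledge
bases.

## The ablation experiment

`kb_ablation()` generates 500 sentences with 4 relation labels, splits
documents 70/30 into train/test, and trains the same architecture with
and without KB attention from identical seeds, five seeds per
condition. Record coverage is set to 1 in this experiment — the
knowledge pathway is the experimental variable, and partial coverage
would cut retrieval off before attention ever sees it. Network
dimensions are scaled (embedding 24, state 16 per direction) and the
schedule is 12 epochs with batch 10: the planted-signal conditions
concern the corpus and the knowledge store, not network width, and the
scaled problem keeps the full 20-run experiment in the test suite.
With `kb_signal = 1, p_trigger = 0` the KB-attentive model separates
the labels through the marker species in its attention memory while
the baseline has nothing to learn from; with `kb_signal = 0` the two
models are byte-identical by construction (empty memory plus shared
initialization and shuffling), so the null comparison is exactly
paired.

```{r ablation, eval = FALSE}
kb_ablation(kb_signal = 1, p_trigger = 0, seeds = 1:5)
kb_ablation(kb_signal = 0, p_trigger = 0, seeds = 1:5)
```

The directionality ceiling is worth noting: attention over a vector
*set* is permutation-invariant, and the textual window of `(a, b)`
equals that of `(b, a)`, so the model cannot distinguish the two orders
of a pair from these features alone. With symmetric gold annotation
this is moot; with strictly directed gold the reverse order caps
micro-F1 near 2/3.

## Numerical and degenerate-input choices

* Softmax always subtracts the maximum logit; adding any constant to
  all attention logits leaves the weights bit-unchanged.
* Empty memory ($V = \emptyset$) returns `h` itself, not a copy with
  arithmetic applied — downstream comparisons are bit-exact.
* Viterbi and argmax ties resolve to the lowest index, so decoding is
  reproducible across platforms.
* Empty sentences are an error for the encoder; empty documents
  predict no relations; an SBML model without `listOfReactions` is a
  model with zero reactions, not an error.
* Duplicate embedding rows keep the first occurrence (with a warning);
  malformed rows are errors that name the offending line.
* LSTM forget-gate biases start at 1; other weights use Glorot limits.

## Known limitations

* The tokenizer is rule-based (whitespace, punctuation peeling, slash
  splitting). It keeps hyphens and digits inside tokens so names like
  `14-3-3` survive, but it performs no POS tagging or lemmatization;
  externally produced POS/lemma columns can be carried on tokens.
* Discontinuous entities are assumed absent and rejected at load.
* The knowledge store is offline by design: it loads exported records
  and SBML files, and never harvests the web.
* Training is single-threaded CPU; the package targets method-scale
  experiments, not large-scale benchmark training.
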