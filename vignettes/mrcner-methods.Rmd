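---
title: "Span extraction for chemical and materials NER: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Span extraction for chemical and materials NER: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcner)
```

## The problem and the reformulation

Named entity recognition in materials-science and chemical text is usually
cast as sequence labeling: one BIO tag per token. That framing has two
structural weaknesses. First, a single tag sequence cannot represent nested
mentions (an inner entity properly contained in an outer one). Second, the
label inventory enters the model only as arbitrary output indices — the
*meaning* of a label ("anything measurable that can have a unit and a
value") is invisible to it.

`mrcner` implements the machine-reading-comprehension reformulation. Each
entity type $y$ gets a natural-language query $Q_y$; each sentence $X =
\{x_1,\dots,x_n\}$ is paired with each query to form a (Context, Query,
Answer) triple, where the answer set is the (possibly empty) set of spans of
type $y$ in $X$. The encoder consumes the combined sequence

$$\{[\mathrm{CLS}], q_1,\dots,q_m, [\mathrm{SEP}], x_1,\dots,x_n,
[\mathrm{SEP}]\}$$

and the model extracts answer spans with a pair of per-position binary
classifiers over the encoder representation $L \in \mathbb{R}^{N\times d}$:

$$K_{start} = \mathrm{softmax}(L\,Q_{start}) \in \mathbb{R}^{N\times 2},
\qquad
K_{end} = \mathrm{softmax}([L\,;K_{start}]\,Q_{end}) \in
\mathbb{R}^{N\times 2}$$

The end head sees the start probabilities (the *conditioned* variant); the
*base* variant drops them, $K_{end} = \mathrm{softmax}(L\,Q_{end})$, and is
kept as an ablation mode. Positive index sets are obtained by row-wise
argmax restricted to context positions:

$$I_{start} = \{i : \arg\max K_{start}^{i} = 1\}, \qquad
I_{end} = \{j : \arg\max K_{end}^{j} = 1\}.$$

Because *every* position can be a start or an end, one query can return
several spans, including spans that share endpoints — which is exactly what
makes nested mentions representable.

## Start–end matching

The literature this package follows rejects naive proximity pairing but
specifies no concrete alternative and trains no matching classifier. The
rule implemented here is deterministic and isolated in one function
(`match_spans()`) so alternatives can be swapped in:

*each end position pairs with the nearest start position at or before it; a
start may serve several ends; a start with no end at or after it is
dropped.*

This supports the nested shared-start case (an inner mention and an outer
mention that begin at the same word, like a material name nested inside a
longer catalyst mention): one start, two ends, two spans. Each span carries
the product of its endpoint class-1 probabilities as a score; no threshold
is applied by default.

## Tokenization, label placement, windowing

Corpora arrive pre-tokenized at word level; a tokenizer contract maps each
word to one or more subword pieces (the shipped `word_tokenizer()` is the
identity; `subword_tokenizer()` splits on hyphens to exercise multi-piece
words). Gold span bits are placed on the **first piece of the start word**
and the **last piece of the end word**. Predictions that land mid-word are
snapped outward to word boundaries before evaluation, which is word-span
exact match.

Contexts longer than `seq_len` (default 512 pieces) are split into windows
with stride 128. An answer is labeled in every window that contains it
wholly; an answer contained in no window is dropped from the labels with a
warning and is still counted against recall — long-context handling is not
described in the source recipe, so this conservative policy is a package
decision. Negative (sentence, type) pairs are kept: the model must learn to
return empty answers, and down-sampling policy is likewise unstated
upstream.

## Losses

Both heads are trained with the same loss, summed without weights (no
combination weights are given upstream):

* **Focal** (default): $-\alpha_t (1-p_t)^\gamma \log p_t$ averaged over
  context positions, $\gamma = 2$, positive-class $\alpha = 0.25$ (the
  original focal-loss convention; both exposed, and `alpha = NULL` gives the
  unweighted form). Focal loss addresses the heavy class imbalance of
  span-boundary bits: almost every position is negative.
* **Cross-entropy**: the $\gamma = 0$, unweighted special case.
* **Label smoothing**: cross-entropy against targets softened to
  $(1-\varepsilon, \varepsilon)$, default $\varepsilon = 0.1$.

With $\gamma = 0$, uniform $\alpha$ and $\varepsilon = 0$ all three
coincide; this identity is property-tested at $10^{-9}$, and analytic
gradients (used by the trainer) are checked against central finite
differences at $10^{-4}$.

A design point worth recording: the conditioned end head consumes
$K_{start}$ in the forward pass, and the gradient **flows through it** (no
detaching). Whether to detach is an open question upstream; not detaching
keeps the computation graph and its gradient consistent, which the
finite-difference check enforces.

## The desk-scale encoder

Published results in this line of work fine-tune a domain-pretrained
transformer; pretraining and checkpoint redistribution are out of scope
here. The encoder is therefore a *contract* (deterministic map from piece
sequences to $\mathbb{R}^{N\times d}$, pluggable by name), and the package
ships two implementations:

* `oracle_encoder()` — reads the gold bits and emits a representation from
  which matched heads reproduce the gold spans exactly. An upper bound used
  to test the decode path, never a model.
* `tiny_encoder()` — the trainable desk-scale stand-in. Each piece gets a
  learned embedding $e_i \in \mathbb{R}^d$ (default $d = 32$); position
  $i$'s representation is

  $$\tanh\!\big(e_{i-1}W_1 + e_iW_2 + e_{i+1}W_3 + \bar q\,W_q +
  (e_i \odot \bar q)\,W_m + b\big)$$

  where $\bar q$ is the mean query-piece embedding. The ±1 window makes it
  bidirectional; the additive $\bar q W_q$ term injects query identity; the
  multiplicative $e_i \odot \bar q$ term makes query–token *agreement*
  linearly readable. The multiplicative term is load-bearing: without it,
  learning the conjunction "this token is of the queried type" through a
  single tanh layer stalls on a substantial fraction of initialization
  seeds, with only some entity types learned.

**Learning rate.** The published fine-tuning recipe (sequence length 512,
batch size 8, learning rate 2e-5, focal loss) is kept as the
`train_config()` default. But 2e-5 is a rate for nudging a pretrained
110M-parameter encoder, and cannot train a from-scratch network in 20
epochs. Each encoder contract therefore declares an `lr_scale` multiplier:
1 for a pretrained-style encoder, 2500 for the tiny encoder (effective peak
0.05). Optimization is AdamW-style (decoupled weight decay 0.01), 10%
linear warmup, then linear decay to a 20% floor — the floor keeps a usable
step size for slow-to-escape initializations. Optimizer, schedule, epoch
count (20) and run count (3) are unstated upstream and are package
defaults. Training is deterministic given the seed; the best-dev-F1 state
is selected, stopping early only when dev F1 reaches 1 (it cannot improve
further).

## The synthetic world

`generate_corpus()` emulates a tagged corpus at desk scale: background
tokens from a background vocabulary, entities as runs of tokens from
per-type vocabularies, all vocabularies pairwise disjoint. Defaults: 500
sentences of 6–12 tokens, four types, Poisson entity density 1.5, entity
length 1–3, no nesting, fixed seed.

Two generator properties are deliberate:

* **A one-token background buffer separates entities.** Two adjacent
  same-type entities are indistinguishable from one longer entity — no
  model, and not even the token-lexicon oracle, could recover the boundary.
  The buffer makes the stated invariant ("a lexicon oracle attains
  F1 = 1.0 on flat corpora") true by construction, and makes "the pipeline
  can learn this world" a falsifiable claim.
* **Nested inner spans always carry a different label than their outer
  span** (and share its start word, the shape of the fixed nested fixture),
  so one query per type retrieves each nesting level cleanly.

What a green test does establish: every pipeline stage — conversion,
encoding, heads, matching, decoding, training, scoring — is internally
consistent and can drive a capable learner to the known ceiling. What it
does not establish: performance on real materials-science text, whose token
distributions, acronym/synonym noise and annotation idiosyncrasies the
generator intentionally does not mimic. The published benchmark F1 scores
require the five external corpora plus pretrained weights and are not
reproduced here.

## Numerical and degenerate-case choices

* Score matrices are validated row-stochastic to $10^{-6}$; probabilities
  are clamped at $10^{-12}$ inside logs.
* Argmax ties (exactly 0.5/0.5) resolve to the negative class.
* Precision/recall with zero denominators score 0 and set a `degenerate`
  flag; run aggregation uses the sample (n−1) standard deviation, 0 for a
  single run.
* Orphan `I-` tags in input BIO are repaired as span starts with a warning
  (public corpora contain scheme noise); `strict = TRUE` raises instead.
* Checkpoints serialize at 17 significant digits, which round-trips IEEE
  doubles exactly and makes experiment replay bit-identical.

## Known limitations

* The tiny encoder's receptive field is ±1 token plus the query summary; it
  is a test vehicle, not a competitive model. Real use requires plugging a
  pretrained encoder into the registry.
* The start–end matching rule is heuristic; a learned match classifier is
  explicitly out of scope.
* Windowed encoding drops boundary-crossing gold spans from training labels
  (counted as misses at evaluation).
* BIO output (`write_conll()`) refuses nested corpora by design; use the
  JSON-lines span format for those.
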