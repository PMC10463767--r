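---
title: "Prescription recommendation from plant EMRs by contrastive sentence embedding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prescription recommendation from plant EMRs by contrastive sentence embedding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pemrec)
```

## The problem

A plant electronic medical record (PEMR) is a consultation note written by a
plant doctor: what the crop looks like, where and when the disease appeared,
and which pesticide prescription was issued. Following the disease-triangle
principle of plant pathology — disease emerges from the interaction of host,
pathogen and environment — a record carries three groups of three text
fields each:

* **environment**: onset date, location, field distribution;
* **plant**: species, growth stage, affected part;
* **symptom**: severity, main symptoms, detailed notes;

plus the **prescription** label. Given a new consultation, the task is to
recommend prescriptions by finding semantically similar historical records.
Treating this as retrieval rather than classification matters in practice:
pesticide catalogues change constantly, and a retrieval system accommodates
a brand-new prescription by simply adding its records to the reference set,
with no retraining — the open-set protocol below probes exactly this.

## The pipeline

1. **Corpus preparation** (`normalize_records`, `serialize_records`,
   `split_dataset`, `build_pairs`). Records are cleaned (whitespace
   collapsing, fullwidth-to-halfwidth folding, prescription aliasing,
   de-duplication), serialized to a single text in the fixed order
   environment → plant → symptom with fields joined by the reserved
   `[FSEP]` token, and split 8:1:1 (stratified by prescription) into a
   training pool, a query set and a reference set. The pool is split again
   7:3 into pair-training and pair-test records. Within each side, all
   unordered record pairs are enumerated and labeled 1 when the two records
   share a prescription; negatives are down-sampled to a 1:1 balance.
2. **Encoding** (`encoder_config`, `init_encoder`, `encode`, `pool`). A
   small bidirectional transformer maps a tokenized record to per-layer
   token representations, reduced to one sentence vector by a pooling
   strategy.
3. **Contrastive training** (`train_encoder`). Both pair texts pass through
   the shared (siamese) encoder; a pairwise objective over their cosine
   similarities is minimized with AdamW.
4. **Retrieval** (`build_index`, `recommend`). Every reference record is
   embedded and L2-normalized; a query is answered by exact exhaustive
   cosine search, and the top-N *distinct* prescriptions are returned.

## Model

Each transformer block applies multi-head scaled dot-product attention

$$\mathrm{Attention}(Q,K,V)=\mathrm{softmax}\!\left(\frac{QK^{\top}}{\sqrt{d_k}}\right)V,$$

with per-head projections $head_i=\mathrm{Attention}(QW_i^q,KW_i^k,VW_i^v)$
concatenated and linearly mapped back to width $d$. The attention equations
alone do not train stably, so each block uses the standard residual
connections, post-layer normalization and a two-layer position-wise
feed-forward sublayer (GELU activation, hidden width $4d$) of the BERT
family the architecture belongs to. Token embeddings are summed with
learned position embeddings; the segment embedding is constant because the
twin-tower design never feeds sentence pairs jointly.

Five pooling strategies reduce token representations to a sentence vector:

* `cls` — the last-layer `[CLS]` row (the default; contrastive training
  updates this token's representation directly);
* `mean` — the mask-aware average of last-layer token rows;
* `first_last_avg` — the average of (first encoder layer + last layer)/2
  over real tokens. Whether "first" means encoder block 1 or the embedding
  layer is genuinely ambiguous in the literature; block 1 is the default
  and `first_last = "embedding"` selects the alternative;
* `pooler` — a dense layer with Tanh applied to the `[CLS]` row;
* `max` — the mask-aware element-wise maximum, included because pooling
  nomenclature varies across reports; all five share one contract
  (padding can never influence the result).

## Training objectives

Let $u$, $v$ be the pooled embeddings of a text pair and
$\cos(u,v)=u\cdot v/(\lVert u\rVert\,\lVert v\rVert)$.

**CoSENT** (default) is a ranking loss over the batch's pair cosines:

$$\mathcal{L}=\log\Bigl(1+\sum_{(i,j)\in\Omega_{pos},\,(k,l)\in\Omega_{neg}}
e^{\lambda(\cos(u_k,u_l)-\cos(u_i,u_j))}\Bigr),$$

summing over every (positive pair, negative pair) combination. It is
computed with a log-sum-exp reformulation that treats the constant 1 as an
extra zero term, so it is finite for any $\lambda\le 100$ and exactly 0
when either side of the cross set is empty (a single-label batch
contributes zero loss and is skipped, not an error). $\lambda$ defaults to
20, the published CoSENT default. Because the loss orders the very cosines
used at inference, training and prediction objectives coincide.

**Supervised SimCSE** is the temperature-scaled contrastive loss
$-\log\frac{e^{\cos(h_i,h_i^+)/\tau}}{\sum_j e^{\cos(h_i,h_j^+)/\tau}+e^{\cos(h_i,h_j^-)/\tau}}$
averaged over anchors, with $\tau=0.05$ by default. The native format of
this loss is the (anchor, positive, hard negative) triad; pair-format
batches are adapted by taking each positive pair as (anchor, positive) and
the second elements of the batch's negative pairs as shared hard
negatives. The unsupervised dropout-augmentation variant is out of scope.

**Sentence-BERT softmax** classifies $(u, v, |u-v|)$ through a trainable
$3n\times k$ head with cross-entropy. It is a training-time objective only;
inference always ranks by cosine. Its known weakness — the training
objective is unrelated to the cosine used at prediction — is what the
CoSENT comparison quantifies, and the package's acceptance suite checks the
direction of that gap.

**Optimization.** AdamW with decoupled weight decay 0.01 applied to weight
matrices only (not biases, layer norms or embeddings), global gradient-norm
clipping at 1.0, batch size 32, 15 epochs, and per-epoch reshuffling with a
derived seed (`seed + epoch`) so runs are reproducible yet batches vary
across epochs. The conventional fine-tuning rate 2e-5 is far too
conservative for a from-scratch encoder of this size; the default is 1e-3,
and 2e-5 remains the documented choice when a pretrained encoder is plugged
in. After every epoch the held-out pair cosines are scored by Pearson and
Spearman correlation against the 0/1 labels; the best checkpoint is the
epoch with the highest Spearman (scale-free, hence robust to cosine
calibration drift), and both final and best checkpoints are kept.

The transformer forward and backward passes are implemented in
RcppArmadillo with sequences stacked row-wise so projections and
feed-forward GEMMs run over whole mini-batches; analytic gradients are
verified against central finite differences in the test suite.

## Retrieval and evaluation

Reference embeddings are stored L2-normalized, making cosine a dot
product; search is exact and exhaustive (reference sets here are at most
tens of thousands of rows, where approximate indexing buys nothing). Ties
are broken by earlier reference row for determinism. Top-N counts
*distinct* prescriptions — duplicated prescriptions among the top rows
would otherwise waste recommendation slots — and each prescription keeps
its best-scoring supporting record. The reference set stores one embedding
per record rather than one per prescription, matching the view that every
historical record is a retrievable case.

`run_protocol` builds the index, serializes queries with a chosen subset of
field groups, and reports Top-n accuracy (hits over queries). A query whose
true prescription is absent from the reference counts as a miss, never an
exclusion — the open-set protocol depends on this. The protocol label is
decided by prescription overlap with the training manifest: `open_set` iff
disjoint. In the field-ablation experiments both the queries and the
reference are serialized with the same reduced groups by default (the
reference side is configurable via `reference_groups`); using matched
serializations keeps the comparison about information content rather than
train/test mismatch. Undefined correlations (constant cosines or labels)
are flagged `NA` with a reason, never silently 0, because a silent 0 would
corrupt best-checkpoint selection.

## The synthetic corpus generator

The PEMR corpora this method was designed for are consultation records held
by plant-protection institutions and are not publicly distributable, so the
package ships a seeded generator (`generate_corpus`, `generate_open_set`)
that emulates their *structure*: latent disease classes, each mapped to one
prescription, each owning disjoint core vocabularies per field group, plus
a shared vocabulary of generic filler tokens. Signal fields draw from the
class core vocabulary with a configurable `noise_rate` of replacement by
shared tokens; non-signal groups draw entirely from the shared pool.
Defaults: 6 tokens per field (texts stay comfortably under the 80-token
cap), core vocabulary 20 per class per group, shared vocabulary 50. A
`share_prescription` mode makes two diseases share one prescription, which
exercises the labeling rule that pairs follow prescriptions, not diseases.
Open-set corpora reuse the shared vocabulary but have disjoint classes and
prescriptions, so the text style transfers while the labels do not.

What the generator does *not* emulate: real agronomic language (dialect,
slang, entry errors), class imbalance, correlated fields, or ambiguous
cases where one symptom pattern admits several prescriptions. Passing the
benchmark therefore shows that the implementation learns and retrieves
correctly under known separable structure — it does not certify accuracy
on real consultation text.

A bag-of-tokens nearest-neighbour oracle (no learned encoder) is checked in
the tests before any encoder benchmark: at `noise_rate <= 0.1` it must
recover classes at ≥ 95%, guaranteeing that the generator emits learnable
signal, and its accuracy must degrade monotonically along the noise grid
{0, 0.3, 0.6, 0.9}.

## Problem sizes and numerical choices

The benchmark used by the acceptance suite and `scripts/acceptance.R`: 8
classes × 60 records at 10% noise, split 8:1:1 (so 48 queries against a
48-record reference), pair pool split 7:3, balanced pairs capped at 800 for
training and 200 for held-out evaluation, encoder `d = 64`, 4 heads, 2
layers, trained 15 epochs. The caps are seeded, balance-preserving
subsamples of the full pair universe; 800 balanced pairs give ~375 AdamW
steps, ample for convergence on this corpus while keeping a full run in the
low minutes on one CPU core. The open-set corpus adds 4 unseen classes
(disjoint prescriptions), split 5:5 into query and reference halves.

The tokenizer vocabulary is fitted on the serialized base *and* open-set
texts. This mirrors the pretrained-tokenizer setting the architecture comes
from, where the vocabulary covers words the fine-tuning data never
contains: open-set tokens get embeddings at initialization that are simply
never updated during training, rather than collapsing onto `[UNK]` (which
would erase the lexical signal that open-set generalization relies on).

Other numerical choices: layer-norm epsilon 1e-5; GELU in its tanh
approximation; parameter initialization normal(0, 0.02) (the convention of
this model family), layer-norm gains 1, biases 0; retrieval scores clamped
to [-1, 1] to absorb float32 rounding in stored indices; stable softmax
(row-max subtraction) everywhere; largest-remainder rounding for split
sizes with ties to the earlier part; a stratum smaller than the number of
parts goes wholly to the largest-ratio part with a warning (preserving rare
prescriptions for training); duplicate detection uses the full serialized
text plus prescription (conservative); empty texts tokenize to the valid
single-token `[CLS]` sequence.

## Known limitations

* The built-in encoder is deliberately small and trained from scratch; it
  demonstrates and tests the method but will not match a fine-tuned
  pretrained Chinese encoder on real PEMRs. External encoders plug in as a
  plain `function(texts) -> matrix` (`as_encode_fn` shows the contract).
* The whitespace tokenizer suits the synthetic corpus; real Chinese text
  needs the plug-in encoder's own subword tokenizer.
* Retrieval is exact and in-memory; far larger reference sets would need
  approximate nearest-neighbour indexing, which is out of scope.
* No significance testing across model variants is performed.
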