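---
title: "Predicting N-terminal targeting peptides and their cleavage sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting N-terminal targeting peptides and their cleavage sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targpep)
```

## The problem

Proteins destined for the secretory pathway, mitochondria, chloroplasts or
the thylakoid lumen carry an N-terminal targeting peptide that is cleaved
after import.  `targpep` jointly answers two questions from the amino-acid
sequence alone: *which* of the five classes a protein belongs to — no
targeting peptide (`noTP`), signal peptide (`SP`), mitochondrial transit
peptide (`mTP`), chloroplast transit peptide (`cTP`), or bipartite
thylakoid luminal transit peptide (`luTP`) — and *where* the peptide is
cleaved.  The cleavage site (CS) is stored as the 1-based index of the
last peptide residue; cleavage occurs between `cs` and `cs + 1`.  Around
the cleavage bond we use the −1/+1 convention (no position 0): −1 is the
last peptide residue, +1 the first mature residue.

For `luTP`s only the second, thylakoidal-processing-peptidase cleavage is
annotated and predicted; the label denotes the entire bipartite signal.

## The model

The first 200 residues of each chain (transit peptides are at most 162
residues long, so the window always covers the peptide) are encoded as
BLOSUM62 substitution-matrix rows, with `X` and all ambiguity codes as the
zero vector.  The network is then

1. a position-wise dense feature transform, `c_t = ReLU(W x_t + b)`
   (32 units by default);
2. a bidirectional LSTM (256 units per direction) whose **initial hidden
   and cell states in both directions are learned affine maps of the
   scalar plant/non-plant flag** — the smallest mechanism that lets
   organism-group information condition the whole encoding;
3. a multi-attention layer over the concatenated hidden states
   `h_t = [h→_t ; h←_t]`: with a shared projection,
   `score_{k,t} = tanh(W_a h_t + b_a) · v_k`, masked positions set to −∞,
   and a softmax over positions per head, giving an attention matrix `A`
   (13 heads by default, each row a distribution over real residues);
4. the first four attention heads are read out **directly** as the
   cleavage-site distributions for SP, mTP, cTP and luTP (the
   cleavage-site read-out is the identity on those rows, so CS training
   shapes the attention itself — this is what makes the attention maps
   interpretable);
5. the context matrix `e_k = Σ_t A_{k,t} h_t` (512 × 13 by default) is
   flattened head-major, summarised by a 256-unit ReLU layer, and a 5-unit
   softmax yields the class probabilities.

Training minimises the mean class cross-entropy averaged with the mean
cleavage-site cross-entropy, the latter taken only over records that carry
a CS and only on the head matching the *true* class (a record has exactly
one annotated CS; the other heads have no target on it).  A batch of only
`noTP` records contributes the class term alone — there is no
cleavage-site error to back-propagate.  At prediction time the class is
the argmax of the softmax and, for a non-`noTP` call, the CS is the argmax
of the matching head; all argmax ties break toward the lower index.

### Design choices made where the design was open

* **Activation of the feature transform**: ReLU.
* **Dropout** (single rate, default 0.25 full-size / 0.1 reduced) is
  applied after the feature transform, after the BiLSTM and after the
  summariser.
* **Context summarisation**: flatten-then-dense is the least-structured
  reading of "summarise the context matrix into a vector".
* **Attention parameterisation**: one shared `tanh` projection with one
  score vector per head.
* **Non-standard residues** (B, Z, J, U, O, and U in particular is *not*
  mapped to cysteine) encode as zero vectors — neutral under the first
  linear layer.
* **Group flag** defaults to non-plant when unknown.

### Implementation and numerics

The layer semantics are defined by plain-R reference functions
(`feature_transform()`, `bilstm_encode()`, `multi_attention()`,
`predict_cs()`, `encode_context()`, `predict_type()`, `tp_forward_ref()`,
`tp_loss_ref()`); training and prediction run through a compiled
RcppArmadillo kernel with hand-derived gradients.  The test suite binds
the two paths together to ~1e−12 and checks every gradient block against
central finite differences.  The backward LSTM runs over reversed,
left-aligned sequences so padding never precedes real residues; forward
outputs beyond a record's length are masked, which makes the forward pass
exactly invariant to the amount of padding.  Probabilities are clamped at
1e−12 inside logarithms; Glorot-uniform initialisation with a +1
forget-gate bias; Adam defaults lr 1e−3, batch 64, patience 5, at most 50
epochs.  All randomness (initialisation, shuffling, dropout, validation
split) derives from a single integer seed, and fitting is bit-reproducible
on CPU.

## Cross-validation and the baseline

Generalisation is estimated with homology-aware nested five-fold
cross-validation: records are clustered at 20% identity over at least 80%
of the shorter sequence (first 200 residues), whole clusters are dealt to
folds (largest first, to the fold currently smallest for the cluster's
majority class), and each outer test fold pairs with four inner
train-3/validate-1 rotations — 5 × 4 = 20 models.  The out-of-fold
prediction of a test record is the **average of its four inner models'
probability vectors** (the spec of nested CV leaves the test-time rule
open; averaging is the standard ensemble reading and preserves
normalisation).  The bundled `cluster_greedy()` is an explicit stand-in
for profile-based clustering: ungapped, 3-mer-seeded diagonal identity
with greedy single-linkage.  It reproduces the intended behaviour on
point-substituted families but will not find remote, indel-rich homology;
a precomputed cluster table can be supplied instead.

`targpep_mlp()` is the MLP-XX baseline: a one-hidden-layer (default 64
units; 0 gives softmax regression) feed-forward classifier on one-hot
encodings of the first XX residues.  It never predicts a cleavage site.

## Evaluation metrics

One-vs-rest precision, recall, F1 and MCC per class, with every
zero-denominator case defined as 0 (unit-tested); confusion matrices are
predicted-by-observed (rows × columns).  Cleavage-site recall at window
`w` is the fraction of records of a class, *among those also classified
into that class*, whose predicted CS lies within `w` residues (two-sided)
of the annotation.  ROC curves are one-vs-rest threshold sweeps; the AUC
is trapezoidal and equals the Mann–Whitney statistic.

## Count correction

For proteome-scale annotation the raw per-class tallies are de-biased
through the confusion matrix: `misprediction_fractions()` estimates
`P(true = c | predicted = k)` by row-normalising, and `correct_counts()`
redistributes each predicted pool, `corrected[c] = Σ_k n_k P[k, c]`.  Row
(predicted-conditional) normalisation is the only orientation under which
totals are conserved exactly and the true per-class counts are recovered
exactly when `P` is estimated on the evaluated set itself; both identities
are tested.  Pools of a class that was never predicted cannot be
redistributed and are left in place with a warning.

## Interpretability analyses

* `attention_profile()` — per-position maximum over attention heads (an
  option returns the full per-head matrix instead).
* `build_logo()` — frequency or attention-mass logo matrices anchored at
  the N terminus or at the cleavage site.  In attention-mass mode the
  letter height of residue *r* at an offset is the mean attention mass
  carried by *r* there, so column totals reproduce the mean profile; the
  caption of this logo style reads as attention-weighted frequencies, and
  that is what is implemented.
* `position2_table()` — frequencies of A, C, G, P, S directly after the
  initiator methionine (the residues that permit methionine excision),
  per class and organism group.
* `nearest_upstream_arginine()` — distance from the CS to the closest
  arginine in the peptide, the signature of the MPP (−2), Icp55 (−3) and
  MIP (−10) processing peptidases.
* `structure_preference_profile()` — log2 mean helix/sheet/turn
  propensities per offset, using the bundled Chou–Fasman scale
  (`inst/extdata/chou_fasman.tsv`, editable so another published scale can
  be substituted; results are scale-relative).

## The synthetic study

Real training data for this problem are experimentally annotated database
extracts.  To make the whole pipeline testable offline, `synth_generate()`
plants the class-defining grammars described for the real peptides:

* **SP** — K/R-enriched n-region (1–5 aa), hydrophobic h-region (7–15 aa
  from L/A/V/I/F), 3–7 aa c-region ending in an A-X-A-style motif (small
  residues at −1 and −3, mostly alanine);
* **mTP** — 15–60 aa, R/L/S-enriched and acid-depleted, with one arginine
  planted at −2, −3 or −10 (equal mixture weights by default) and an
  otherwise arginine-free final ten positions, so the planted offset *is*
  the nearest upstream arginine;
* **cTP** — 30–80 aa, S/T-enriched and acid-free, alanine at position 2
  with probability 0.65 (the reported two-thirds);
* **luTP** — a 15–40 aa cTP-like stretch followed by an SP-like stretch,
  with the CS at the end of the second stretch only;
* **noTP** — background composition throughout; mature regions of 60–150
  aa are appended to every peptide.

Background frequencies are uniform over the 20 residues, which keeps the
chance floor of the classification problem analytic (the majority-class
share).  cTP/luTP records are assigned to the plant group, other classes
evenly to both.  These parameters were fixed when the generator was
written and are deliberately *not* tuning knobs.

What passing on this study shows — and what it does not: the synthetic
grammars are compositionally clean, indel-free and far more separable
than real peptides, so out-of-sample scores here demonstrate that the
architecture, losses, gradients and evaluation machinery work end to end,
not that the package reaches any particular accuracy on real proteins.
Conversely the analyses recover exactly the planted signals (position-2
alanine ≈ 0.65, arginine modes at −2/−3/−10, attention peak at the CS),
which validates the analysis code by parameter recovery.

## Problem sizes used in the shipped experiments

The default end-to-end experiment — also what `scripts/acceptance.R`
reruns — uses 2,500 training plus 500 test records (class mix 50% noTP,
20% SP, 15% mTP, 10% cTP, 5% luTP) and a reduced configuration (feature 16,
LSTM 64, attention 32 × 8 heads, summariser 64, dropout 0.1, ≤ 15 epochs):
large enough that all five classes and both CS signal types are learned,
small enough to train in a few minutes on one CPU core.  Invariant and
oracle tests run on miniature configurations (4–8 units) where finite
differences are accurate and exhaustive checks are cheap.

## Known limitations

* The published trained weights are not reproduced; only the method is.
* `cluster_greedy()` underestimates homology with indels (by design — it
  is a stand-in; supply a real clustering for serious partitioning).
* The attention/CS coupling means a misclassified record's CS comes from
  the argmax head of the *predicted* class; windowed CS recall therefore
  conditions on correct classification, as is standard for this task.
* Checkpoints are RDS files, readable only from R.
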