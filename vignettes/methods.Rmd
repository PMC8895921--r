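---
title: "Models and methods behind sigddi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sigddi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sigddi)
```

# Overview

`sigddi` predicts polypharmacy side effects for drug pairs in two stages.
A *feature generation* model maps compound structure and properties to a
predicted 978-landmark-gene differential-expression signature, so that
every compound — profiled or not — has a transcriptional representation.
A *DDI prediction* model consumes the two signatures of a pair, produces
pair-conditional latent representations through a gated linear unit
(GLU), and scores the pair against each side effect with a translating-
embedding distance trained under a margin ranking loss. This vignette
documents the models, their assumptions, the tunable parameters, the
synthetic worlds used for verification, and the numerical and design
choices made where the problem statement left room.

# The expression-generation model

## Architecture and loss

Two input branches — one for the binary Morgan fingerprint (default
radius 2, 2048 bits), one for the min–max-scaled descriptor vector — each
pass through a dense layer (defaults 512 and 64 units), optionally batch
normalization, and a ReLU. The branch outputs are concatenated and mapped
linearly to the 978 landmark genes. The loss is the element-wise mean
squared error between predicted and measured signatures; L2 weight decay
(default `1e-4`) and batch normalization counter overfitting, since
feature dimension is comparable to realistic training-set sizes. The
optimizer is Adam under a cosine-annealing schedule

$$\mathrm{lr}(t) = \mathrm{lr}_{\min} + \tfrac12(\mathrm{lr}_{\max} -
\mathrm{lr}_{\min})\bigl(1 + \cos(\pi (t \bmod T)/T)\bigr),$$

restarting every $T$ epochs (defaults $10^{-3}$ to $10^{-5}$, $T = 50$)
— the restarts help escape shallow minima in the non-convex fit.

With `folds > 1` the fit uses k-fold cross-validation (default 10): every
compound is predicted exactly once out-of-fold, and the deployed model is
then retrained on the full data, which matters when data are scarce
relative to the feature dimension.

## Evaluation metric

Reported recovery is the Pearson correlation between predicted and true
signatures. Correlation can be taken per gene (across compounds) or per
compound (across the 978 genes); the package implements both and defaults
to **per compound**, since the question the model answers is "how well is
*this compound's* expression response predicted?". The choice is a
config switch (`metric`).

## Assumptions

* One signature per compound: multiple experimental conditions are
  collapsed beforehand by selecting the candidate with maximal *signature
  strength* (the count of genes with |z| at or above a threshold, default
  2), ties broken by first occurrence. Cell-line heterogeneity is not
  modeled.
* Descriptors are scaled to [0, 1] on a *reference* compound set (the
  training set of the expression model); values of external compounds
  falling outside the reference range are clipped into [0, 1], keeping
  the model's input domain closed. Constant reference features map to 0
  with a warning.
* Descriptor selection fits one random forest per gene target and ranks
  descriptors by impurity importance averaged over targets (ties broken
  by ascending column index). What the forests should predict was an open
  choice; regressing on the expression matrix itself was chosen because
  the selected descriptors exist to serve expression prediction.

# The DDI prediction model

## Pair-conditional gating

Each drug's signature $e \in \mathbb{R}^{978}$ is encoded by a shared
dense layer, $h = \phi(W_1 e + b_1)$. The co-administration effect is a
GLU gate computed from the *ordered* concatenation of self and partner:

$$g_i = \sigma(W_g [h_i ; h_j] + b_g), \qquad
  z_i = W_r (h_i \otimes g_i) + b_r,$$

with all weights shared between the two drugs and the self-first
convention. This makes pair reversal an **exact** symmetry: swapping
drugs swaps $(z_i, z_j)$ bitwise, and the score below is symmetric by
construction. A single order-sensitive gate over $[h_i ; h_j]$ would
break this; reports of near-but-not-exact reversed-pair score agreement
in trained models of this family suggest order-sensitive
implementations exist, but exact symmetry was preferred here as the
semantically correct default. The gate width equals the encoder width
$H$; the default $H = 978$ keeps gate entries aligned with the
landmark-gene order, which is what `gene_attention()` exploits. Gates
are mathematically in $(0,1)$, though extreme logits can round to 0 or 1
in double precision.

## Translating-embedding score and loss

Each side effect $r$ owns a relation vector and two projection matrices
$(M_{rh}, M_{rt})$, and a pair scores

$$S(d_i, d_j, r) = \lVert M_{rh} z_i + r - M_{rt} z_j \rVert_2 +
                   \lVert M_{rh} z_j + r - M_{rt} z_i \rVert_2,$$

summing both directions because drug pairs carry no directionality.
Lower distance means a more plausible interaction; ranking metrics are
computed on negated scores.

The training objective is a margin ranking loss. As printed in the
source material, the loss sums *all* positive scores and *all* negative
scores of a relation inside a single hinge; that aggregate form
degenerates when class sizes differ and does not actually enforce a
per-pair margin. The default here is therefore the standard hinge over
matched (positive, negative) pairs,
$\max(0, S^+ - S^- + \text{margin})$, averaged per epoch with a fresh
seeded matching; the printed aggregate form remains available via
`loss_form = "aggregate"`. The margin defaults to 1.

Widths not fixed by the method description default to reduction width
$D = 128$ and embedding width $E = 64$; all are configurable. The
recovery benchmarks in the tests and acceptance script use the compact
$H/D/E = 128/32/16$ with 500 full-batch Adam epochs, which fits the
planted worlds' complexity and keeps a full run within minutes on one
CPU.

## Cold-start prediction

Drugs enter the model only through their expression features — there is
no drug-identity embedding table. Consequently any drug with a (real or
generated) signature can be scored, which is what the one-unseen and
both-unseen regimes test. Side effects, by contrast, are closed-world:
scoring an unknown side-effect id is an error.

## Ablation hooks

Two switches mirror the model's own component analysis:
`gate = "open"` forces all gates to 1, removing the co-administration
module; `score = "mlp"` replaces the translating-embedding scorer with a
plain feed-forward classifier head (shared hidden layer, per-side-effect
output weights, symmetrized over both pair orders) trained under the
same ranking loss. On the planted worlds, removing the embedding scorer
costs more AUC than opening the gates — the planted truth *is* a
translating embedding, and the gates carry no planted signal, so this
direction is expected there and is asserted only qualitatively.

# Split protocols and negative sampling

*Unseen interaction*: unordered triplets are split 9:1 into train and
test, then 1% of train becomes validation; all three sets are disjoint
as unordered triplets. *One-/both-unseen*: a fraction of the drug
vocabulary (default 0.2, a config parameter — the fraction used
originally is not stated) is held out; test triplets contain exactly one
resp. both held-out drugs, and train contains none.

Negatives are sampled per positive $(d_i, d_j, r)$ by corrupting the
partner with a uniform draw from the vocabulary, rejecting self-pairs,
known positives, and duplicates, giving a 1:1 ratio. Because pairs are
unordered, the anchor kept fixed is drawn at random from the pair — with
a fixed anchor, densely connected hub drugs can exhaust their eligible
partners in dense worlds. Sets are kept exclusive by passing previously
used triplets through `exclude`. Negatives are fixed per set (not
resampled per epoch) so that evaluation is reproducible.

Reversed-pair augmentation (`add_reversed_pairs()`) emits both orders of
every record for training-time consumption and is idempotent. With the
default exactly-symmetric architecture it is redundant (both orders give
identical scores and gradients) and the pipeline omits it; it exists for
order-sensitive variants.

# Evaluation

Metrics are computed within each side effect and macro-averaged with
equal weight. AUC is the Mann–Whitney probability (ties count ½); AUPR
uses step-wise average-precision integration (trapezoids would
overstate it); both are verified against brute-force enumeration
oracles in the tests. The classification threshold per side effect
maximizes Youden's J over midpoints of sorted unique scores (ties to
the lower threshold) — the criterion behind "optimal threshold" was not
named, and Youden's J is the standard choice; thresholds can be chosen
on validation scores and applied to test. Side effects with a single
class in the test set are excluded with a warning.

External validation labels a pair positive when strictly more than a
cutoff (default 65) of its side effects are predicted positive,
mirroring the mean side-effect count per interacting pair in the
FAERS-derived data. The permutation test draws `n_perm` samples without
replacement and reports $p = (1 + \#\{\text{null} \ge
\text{observed}\})/n_{\text{perm}}$, floored at $1/n_{\text{perm}}$ and
capped at 1 — chosen so that an observation exceeding every null draw at
$n_{\text{perm}} = 10{,}000$ reports exactly 0.0001.

# Synthetic worlds

`simulate_expression_world()` draws Bernoulli(0.3) fingerprint bits and
uniform descriptors (defaults: 500 compounds, 32 + 18 = 50 features) and
produces signatures through a planted linear (or shallow tanh) map with
coefficients scaled to a per-gene signal SD of about 2 — the spread of
z-score-like differential expression — plus Gaussian noise (default SD
0.5). `simulate_ddi_world()` (defaults: 60 drugs, 8 side effects, 20%
positive pairs per side effect, no label noise) samples true drug
latents and per-side-effect translating-embedding parameters, scores
every pair with the exact two-direction distance, and labels the
lowest-scoring quantile positive — a quantile, not a fixed threshold, so
every side effect has the configured prevalence. Drug expressions are a
fixed random linear embedding of the true latents, so the planted
structure is recoverable from the features.

What passing recovery shows: the implementation can fit and generalize
the functional forms it claims to implement, at the configured noise.
What it does not show: performance on real LINCS/FAERS data, whose
signature distributions are heavy-tailed and cell-line-confounded, whose
side-effect prevalences are far sparser and imbalanced, and whose
structure-to-expression relationship is far from linear. The planted
worlds deliberately do not emulate those properties beyond Gaussian
noise.

# Numerical choices and degenerate inputs

* All randomness flows from explicit integer seeds through a
  deterministic seed-derivation helper; identical configurations yield
  identical parameters, splits and scores.
* Gradients of both networks are exact (verified against central finite
  differences in the tests, including the batch-norm and both ablation
  paths). Norm gradients guard against division by zero at coincident
  embedding points.
* Ties break deterministically everywhere: ascending column index in
  descriptor selection, first occurrence in representative-signature
  selection, gene order in attention top-k, lower threshold in Youden
  scans.
* Degenerate inputs fail loudly: unparsable SMILES, all-missing
  descriptor columns, zero-variance vectors in Pearson correlation,
  single-class label vectors, saturated negative sampling, and drugs
  without expression features all raise errors naming the offender.
* Out-of-range descriptor values on non-reference compounds are clipped
  to [0, 1]; constant features map to 0 with a warning.

# Problem sizes used in the checks

The recovery benchmarks use 500 compounds (noise SD 0.5, 250 epochs,
single 9:1 hold-out) for the expression model and 60 drugs × 8 side
effects with compact widths (128/32/16, 500 epochs) for the DDI model —
sizes at which the planted structure is comfortably identifiable and a
complete run of the test suite and acceptance script takes minutes on a
single CPU. Cross-validation machinery is exercised at smaller sizes.

# Known limitations

* The full Mordred descriptor set (1826 descriptors) is not computed;
  the built-in set is a lightweight 2-D collection via Open Babel plus
  graph-derived counts, with the descriptor provider pluggable and an
  externally supplied descriptor list honored when available. No
  conformer generation: 3-D descriptors are flagged `NA`.
* Layer widths reported only in supplementary material of the source
  work are unavailable; the defaults here are reasoned placeholders and
  fully configurable.
* The ring count in the built-in descriptors is the cyclomatic number,
  which assumes a connected molecular graph.
* Full-batch training is tuned for desk-scale worlds; realistic
  TWOSIDES-scale training (millions of triplets) would need minibatched
  epochs and sparse bookkeeping that are out of scope here.
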