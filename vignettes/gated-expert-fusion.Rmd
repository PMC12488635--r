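---
title: "Gated mixture-of-experts fusion for phage-host interaction prediction"
author: "phageMoE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gated mixture-of-experts fusion for phage-host interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phageMoE)
```

## The problem and the model

Matching a bacteriophage to the bacterial strain it can infect is the
central computational step of phage therapy against antibiotic-resistant
infections. The wet-lab ground truth is an immersion assay: phages are
exposed to host cultures and a continuous infection score is recorded in
a host × phage matrix. Scores strictly above 1.5 are treated as
significant infection (label 1), scores at or below 1.5 as no
significant infection (label 0); the boundary value 1.5 itself, which
the thresholding convention leaves open, is assigned to class 0 here
(strict "above") and this choice is fixed throughout the package.

Each phage-host pair is represented by three feature blocks:

* **Statistical descriptors** (`s = 26` values): the amino acid
  composition (20 residue frequencies, `AAC_i = n_i / L`), the atomic
  composition (fractions of C, H, N, O, S atoms over the residues'
  elemental formulas, `AC_j = a_j / sum_k a_k`), and the molecular
  weight `MW = sum_i n_i M(A_i)`. The mass table holds average masses
  of the *free* amino acids and the atom counts their molecular
  formulas, because the MW formula is a plain weighted sum with no
  water-loss correction — this makes MW exactly additive under
  concatenation, a property the test suite asserts. The AAC block is
  ordered alphabetically by one-letter code, then C,H,N,O,S, then MW;
  the ordering is arbitrary but fixed and documented so vectors are
  reproducible.
* **Two expert embedding streams** (`d` values each, `d = 1024` for
  production protein-language-model embeddings): high-dimensional
  per-entity vectors consumed through a provider contract. The package
  never trains or ships a language model; embeddings come either from
  a precomputed table (TSV) or from the deterministic synthetic
  provider used throughout the tests.

The model is a two-expert mixture with a sample-specific router. A
two-layer gating network reads the interpretable block and produces a
softmax pair of expert weights,

$$H = \mathrm{ReLU}(X_{\text{stats}} W_1 + b_1), \quad
  G = H W_2 + b_2, \quad
  \alpha = \mathrm{softmax}(G),$$

with `W1` of shape s × 64, `W2` of shape 64 × 2 (hidden width 64 by
default, configurable). The two embeddings are fused by the per-sample
convex combination
$x_{\text{fused}} = \alpha_1 x^{(1)} + \alpha_2 x^{(2)}$
and concatenated with the statistical block, giving a combined vector
of width `d + s` (1050 under the published defaults; all widths derive
from configuration, never from constants). A small 1D CNN — conv
blocks of (convolution, ReLU, batch normalization, max pooling), a
global average pool, a fully connected ReLU layer with dropout, and a
two-logit output — classifies the combined vector. Gate and CNN are
trained **jointly**: the fusion sits inside one computational graph,
so the cross-entropy gradient flows through the combined vector and
the softmax into the router. The per-sample $\alpha$ is also the
model's explanation: it says which expert stream the router trusted
for that pair.

## Why the numerics are hand-written

No automatic-differentiation framework is used: the forward and
backward passes (im2col convolution, batch-norm statistics and their
gradients, argmax-cached max pooling, inverted dropout) and the Adam
optimizer are implemented in vectorized base R. This keeps the joint
gate + CNN update — the method's core — fully transparent and
dependency-free. Correctness is enforced by a finite-difference
gradient check in the test suite that compares every parameter group
(conv, batch norm, fully connected and all four gate tensors) against
central differences on a toy graph; agreement is at the level of the
finite-difference error itself (about 1e-7 in relative terms).

Numerical choices worth knowing:

* Softmax (gate and classifier) is computed max-shifted; the gate
  remains exact for logits of magnitude hundreds.
* The loss is the literal mean binary cross-entropy on probabilities,
  clamped at 1e-12 before the logarithm. The fused log-softmax form is
  numerically preferable in general; the two agree to rounding on real
  logits and the suite asserts that equivalence. The training gradient
  uses the standard softmax cross-entropy form `p - y`, which is
  algebraically identical.
* Batch normalization uses population variance over (batch ×
  positions) per channel, epsilon 1e-5, running-statistic momentum
  0.1; inference uses the running statistics, so prediction is
  batch-size invariant (asserted).
* Max-pool ties resolve to the first position; pooled tails that do
  not fill a window are dropped. Building a network whose pooling
  stack would reduce the signal width below 1 is an error naming the
  offending block.
* Training aborts with a diagnostic if the loss ever becomes
  non-finite.
* Prediction uses `p >= 0.5` for class 1, so the boundary probability
  0.5 predicts an interaction.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` | 1.5 | infection-score cut; strictly greater scores are positive |
| `pairMode` | `"mean"` | phage/host combination; `"mean"` keeps the per-entity widths (26 / d), `"concat"` doubles them |
| `d` | 1024 (production), 16 (desk scale) | expert embedding width; both streams must agree |
| `hidden` | 64 | gate hidden width |
| `channels` | 32, 64 | conv channel widths (kernel 3, same padding) |
| `fcWidth`, `dropout` | 64, 0.3 | fully connected head |
| `lr`, `batchSize`, `epochs` | 1e-3, 32, 50 | Adam training loop |
| `sampling` | `"raw"` | `"over"` duplicates minority rows, `"under"` subsamples majority rows, both to exact equality |
| `folds` | 3 | stratified cross-validation folds |

The pair combination defaults to the element-wise mean because the
published widths (26, 1024, combined 1050) describe one entity-width
vector per pair; concatenation is available when a direction-aware
representation is wanted. Multi-protein entities are reduced to one
vector by mean pooling over their proteins (max pooling is available);
the reduction is not pinned down by the source protocol, and the mean
is the standard per-protein-to-organism choice. The gate consumes the
same min-max-normalized statistical block the classifier sees, so its
logits are scale-stable; feeding it raw descriptors (MW is in the
thousands while compositions are fractions) would let a single feature
dominate the hidden layer.

## Leakage, resampling and `paperMode`

The default pipeline splits stratified folds **first** and only then
resamples and fits min-max normalization on the training portion, so
no duplicated positive can span the train/test boundary and no test
statistic leaks into the scaler. The test suite asserts zero identity
overlap between resampled training sets and test folds. Min-max
parameters map the fitted range to [0, 1], constant features to 0, and
out-of-range test values are deliberately not clipped.

`paperMode = TRUE` instead resamples and normalizes globally before
splitting. Balanced-by-duplication protocols evaluated this way can
show near-perfect sensitivity because copies of the same positive pair
appear on both sides of the split; the option exists precisely so that
the difference between the two protocols can be measured rather than
argued about.

Metrics come from literal confusion-count formulas; a metric with a
zero denominator is reported as `NA` with the undefined-fold count
carried through aggregation — degenerate folds are a real phenomenon
under heavy imbalance and coercing them to 0 would bias fold means.
AUROC uses the tie-aware rank (Mann-Whitney) statistic, which equals
the exhaustive pairwise-comparison probability; AUPR uses the
non-interpolated step-area (average-precision) dialect. Both dialects
are fixed by oracle tests because the defining integrals do not pin
down a discretization.

## What the synthetic generators emulate — and what they do not

All fixtures are generated in code from a seeded `fixtureSpec`; no
data files ship with the package.

* `genEntities` / `genInteractionMatrix` emulate the *shape* of an
  immersion screen: entities with several protein sequences over the
  20-letter alphabet and a continuous score matrix straddling 1.5 with
  a configurable positive fraction (validated to [0.02, 0.98]; values
  outside leave a class empty at desk scale). Scores are drawn
  **independently of the sequences**, so this fixture carries no
  learnable signal by construction: cross-validated AUROC near 0.5 on
  it is the expected outcome and doubles as a negative control for
  leakage (a leaky pipeline scores far above chance on pure noise).
* `genSeparableDataset` plants a margin-separated linear rule on the
  feature blocks; it measures whether the joint optimization can fit
  a clean signal at all (the suite requires at least 0.95 training accuracy
  within 50 epochs).
* `genSpecializationDataset` plants *routing* structure: a binary flag
  in the statistical block decides whether the label follows
  `step(w·expert1)` or `step(w·expert2)`, with one shared unit weight
  vector `w` and boundary-hugging draws rejected below a margin of
  0.5. A single shared `w` is used because it makes the fused vector
  informative under either routing, isolating the router's job;
  distinct per-expert weight vectors would confound routing recovery
  with representation learning. After joint training the mean α₁ among
  flag-1 samples must exceed the flag-0 mean by at least 0.1 — the
  suite observes gaps several times larger.

None of the generators model receptor biology, genome composition or
phylogenetic correlation between entities, so passing tests demonstrate
the *mechanism* (joint trainability, specialization recovery,
leak-free evaluation), not field performance on real screens. Real
immersion datasets with their pre-trained embeddings are consumed
through the same FASTA / CSV / TSV interfaces.

## Problem sizes and reproducibility

Desk-scale runs in the test suite and the acceptance script use
embedding width 16 (8 for toy cases), screens of a few hundred pairs,
3-fold cross-validation and the default 50-epoch budget; the
specialization scenario uses 400 samples and 60 epochs. These sizes
were chosen so that every property is exercised end-to-end in seconds
while remaining comfortably above the regime where class counts per
fold degenerate. Every random draw — sequence generation, score noise,
embedding content, initialization, shuffling, dropout, resampling,
fold assignment — descends from explicit integer seeds, and the
synthetic embedding provider is content-addressed (a pure function of
seed and sequence content), so entire experiment directories are
byte-reproducible across processes; the suite asserts byte-identical
metrics JSON for repeated runs.

## Known limitations

* Exactly two experts in the public API (the internals are written
  over a weight vector, so a K-expert extension is a configuration
  change, not a rewrite); no sparse/top-k routing or load-balancing
  losses.
* The CNN trains on one CPU core; at `d = 1024` with tens of
  thousands of pairs, training is minutes rather than seconds, and no
  GPU path exists.
* Threshold-based labelling assumes one global score scale across the
  screen; batch effects between assays are out of scope.
* Undefined metrics propagate as `NA`; downstream consumers must be
  NA-aware (the provided aggregation is).
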