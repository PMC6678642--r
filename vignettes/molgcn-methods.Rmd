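---
title: "Graph-convolutional property regression with molgcn: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-convolutional property regression with molgcn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molgcn)
```

## The model

`molgcn` predicts continuous molecular properties (ADME endpoints such as
log10 microsomal clearance, log10 solubility, or logit percent-of-control)
directly from a molecule's atoms, bonds and 3D coordinates, with no
hand-engineered descriptors. The architecture has four stages.

**Featurization.** Every atom becomes a 33-vector: a 23-slot element one-hot
(22 named drug-relevant elements plus an "other" bucket), van der Waals and
covalent radii, the number of perceived rings of each size 3-8 containing the
atom, an aromatic flag, and the formal charge. Every *neighbor pair* (a, b)
becomes a 5-vector: a bond-category one-hot over {Single, Double, None}, the
Euclidean distance in Angstrom, and a same-ring flag. Neighborhoods combine
chemistry and geometry: the neighbors of an atom are its bonded partners plus
all atoms within 4.0 Angstrom, truncated to the 12 nearest (bonded atoms are
never dropped) and symmetrized. The "None" bond category exists precisely so
that spatially close but unbonded pairs can carry information.

**Convolution.** Layer $k$ updates each atom $a$ from its neighbors with a
single shared filter:

$$T^k_{a,b} = f\!\left(W^k\,\mathrm{concat}(A^k_b, P_{a,b}) + B^k\right),$$

where $f$ is LeakyReLU with negative slope $\alpha = 0.01$. The
variable-sized set $\{T^k_{a,b}\}$ is collapsed by a *commutative* reduction
— the concatenation of elementwise max, sum and average — and the result is
concatenated back onto the incoming state:

$$R^k_a = \mathrm{concat}\{\max, \Sigma, \mathrm{avg}\}\{T^k_{a,b}\},
\qquad A^{k+1}_a = \mathrm{concat}(A^k_a, R^k_a).$$

The skip concatenation gives every layer direct access to all earlier
representations; widths therefore follow $d_{k+1} = d_k + 3\,d_t$. Pair
features are never updated. After each layer, batch normalization is applied
across all atom states in the batch.

**Pooling and head.** Atom states are pooled with the same Max/Sum/Avg
reduction into a fixed-length molecule embedding (length $3 d_K$), which a
LeakyReLU dense stack maps to one linear output per endpoint. Because every
aggregation step is commutative, predictions are invariant to atom order by
construction; the test suite asserts this to $10^{-4}$ over random
relabelings.

**Multi-task learning.** Several endpoints share the trunk and embedding;
the loss is $\sum_t w_t \cdot \mathrm{MSE}_t$, each task's MSE computed only
over examples where that endpoint was measured (missing labels are masked,
never imputed). This lets a large, well-measured assay stabilize the
representation used by a small noisy one.

**Ensemble fine-tuning.** Stochastic training makes single checkpoints
noisy. A pool of models from different architectures is scored on held-out
validation data; the top k are frozen, and a second-stage model encodes each
member's (embedding, prediction) pair, reduces across members with the same
order-invariant Max/Sum/Avg operator, optionally appends an explicit
descriptor vector, and regresses through a small head. Only the second-stage
parameters train.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `distance_cutoff` | 4.0 A | spatial neighbor radius |
| `max_neighbors` | 12 | per-atom neighbor cap (bonds exempt) |
| `n_conv_layers`, `transform_widths` | 3, 64 | depth and filter width |
| `head_widths` | 256, 128 | dense head |
| `alpha` | 0.01 | LeakyReLU negative slope |
| `bn_momentum`, `bn_eps` | 0.1, 1e-3 | batch-norm tracking and floor |
| `learning_rate` | 1e-3 | Adam step size (beta = 0.9/0.999) |
| `atom_budget` | 2000 | total atoms per packed batch |
| `val_fraction`, `patience` | 0.1, 20 | chronological hold-out, early stop |
| `bn_freeze` | 0.5 | fraction of epochs after which BN statistics freeze |

The 4.0 A cutoff covers 1-2 bonded shells plus through-space contacts at
typical organic bond lengths (1.2-1.8 A); 12 neighbors is rarely binding for
drug-like molecules but bounds the cost of the segment reduction. Aromatic
bonds are Kekule-assigned to Single/Double and triple bonds map to Double,
because the pair schema admits only three bond categories; formal (not
partial) charge is used so featurization needs no electrostatics model.

## Dynamic batching

Molecules vary in size, so batches are packed under an *atom budget* rather
than a fixed count: examples are shuffled (seeded), sorted largest-first and
first-fit packed so no batch exceeds the budget. Per-atom segment ids let
one flat matrix multiply serve the whole batch; unpacking is exact, and
eval-mode predictions are identical (to 1e-5) whether a molecule is scored
alone or packed arbitrarily — asserted in the tests.

## Numerical choices

- **Batch-norm placement and inference.** Normalization acts on the full
  concatenated state after each layer (the alternative — normalizing only
  the fresh reduction block — is equally defensible; we chose the full
  state and document it). Inference always uses running statistics, which
  makes predictions deterministic and batching-independent. The variance
  floor `bn_eps` defaults to 1e-3 rather than the usual 1e-5: atom states
  contain near-constant channels (rare element one-hots, ring counts of
  acyclic batches), and with a tiny floor the factor
  $1/\sqrt{\mathrm{var} + \epsilon}$ amplifies them several-hundred-fold,
  making eval-mode predictions (running statistics) diverge badly from
  train-mode behavior; 1e-3 caps the gain at ~30x and restores a stable
  train/validation relationship.
- **Batch-norm freezing.** Halfway through the epoch budget
  (`bn_freeze = 0.5`) the running statistics freeze and later epochs train
  against them — exactly the normalization inference will use. This
  matters most for masked multi-task training: a small task's final-layer
  readout is a thin direction in feature space, tuned from few examples
  per batch; if those features keep shifting between batch and running
  statistics, the readout that minimizes train-mode loss transfers poorly
  to eval mode (we observed small-task test R² collapsing to ~0.1 while a
  linear readout of the frozen eval-mode features reached 0.74). Early
  stopping receives a fresh patience budget at the freeze transition,
  since the regime change briefly raises the validation loss.
- **Multi-task validation.** With several endpoints, the early-stopping
  hold-out is the newest `val_fraction` of *each task's labeled examples*
  (their union), not of the examples overall: when a small assay's labels
  sit on older compounds, a global newest-slice would contain no
  small-task labels and model selection would silently ignore that
  endpoint.
- **Empty neighbor sets** reduce to a zero block, keeping widths fixed;
  single-atom molecules are valid inputs end to end.
- **Max-reduction ties** route the gradient to the first maximizer.
- **Initialization** is He-style uniform fan-in scaling, seeded; Adam uses
  bias-corrected moments; training aborts with a diagnostic on a non-finite
  loss rather than continuing from a poisoned state.
- **Checkpoints** are single JSON files with parameters serialized as
  `%.17g` strings, so a save/load round trip reproduces eval outputs bit
  for bit.
- **R-squared** is the squared Pearson correlation (the common QSAR
  convention, invariant to affine miscalibration); the coefficient of
  determination is available via `method = "determination"`. Fold accuracy
  counts `|pred - obs| <= log10(fold)` inclusively.
- **Censored assay values** (`<x`, `>x`) keep the numeric bound and set a
  `censored` flag rather than being dropped; duplicates are averaged on the
  raw scale before transformation.

## The synthetic study fixture

Real ADME datasets are proprietary, so the package ships a generator whose
output exercises every code path with a *known* ground truth:

- **Molecules** are valence-respecting random heavy-atom trees over
  {C, N, O, S, F, Cl}, 6-16 atoms, with a 0.3 probability of one 3-6
  membered ring closure and a 0.15 chance of upgrading a bond to double
  where valence allows. Coordinates come from a deterministic spring layout
  targeting 1.5 A bonds; registration dates follow generation order so
  chronological splitting is meaningful.
- **Labels** are additive atomic contributions
  $y = \sum_a c(\mathrm{element}_a) + \varepsilon$. This is deliberately
  the easiest family a graph network must master: if training cannot
  recover an additive property, nothing harder is credible. The default
  noise is $\sigma = 0.3$ against a roughly unit-variance structural
  signal — of the order of assay noise after log transformation; the
  parameter-recovery study uses $\sigma = 0.1$ at n = 1000 train / 200
  test as its fixed condition.
- **Correlated tasks** mix a standardized latent additive property with
  per-task idiosyncratic ones as
  $y_t = \sqrt{\rho}\, z^* + \sqrt{1-\rho}\, z_t + \varepsilon_t$. The
  idiosyncratic parts are Gram-Schmidt residualized against the latent and
  each other on the generated set: random contribution tables are far from
  orthogonal on the same molecules (composition and size dominate), and
  without residualization the realized inter-task correlation can exceed
  0.4 even at $\rho = 0$. Since linear combinations of additive properties
  are additive, the ground truth stays exactly additive. The number of
  mutually orthogonal tasks is bounded by the alphabet size; with six
  elements, up to ~5 tasks are supported.

What the fixture does *not* emulate: realistic chemistry (synthesizability,
stereochemistry, tautomers), conformer ensembles, partial charges,
activity-cliff-like sharp nonlinearities, or assay batch effects. Passing
the recovery and multi-task checks therefore demonstrates that the
architecture, gradients, masking and ensembling are implemented correctly —
not that any particular real-world R-squared will be achieved.

## Study problem sizes

The end-to-end checks run at sizes chosen to make their claims meaningful
while staying desk-scale: 1200 generated molecules (1000 train / 200 newer
test) for parameter recovery and ensembling; a 1000-example auxiliary task
backing a 100-example small task ($\rho = 0.8$) compared over four seeds for
the multi-task effect; compact networks (1-2 conv layers, width 8-16) whose
capacity comfortably covers the additive ground truth. The full-size default
architecture (3 x 64 with a 256/128 head) is exercised for correctness by
the unit tests and available unchanged for real data.

## Known limitations

- Conformer generation is delegated to OpenBabel when only SMILES are
  given; the network consumes whatever single conformer it is handed, and
  prediction quality on real data will inherit conformer quality.
- Batch normalization with very small batches (a handful of molecules) uses
  noisy statistics; prefer atom budgets that hold tens of molecules.
- Aromaticity perception without input annotations is heuristic
  (annotated aromatic bonds, or alternating Kekule 6-rings); exotic
  aromatic systems should arrive annotated.
- The ensemble requires all members to share the endpoint set; heterogeneous
  base learners are out of scope.
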