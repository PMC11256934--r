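---
title: "Path-based heterogeneous graph imputation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path-based heterogeneous graph imputation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pathimpute)
```

## The problem

Spatial transcriptomic platforms measure a cell-by-gene count matrix
`X_obs` (n cells, m genes) together with 2-D coordinates `C`, but the
counts are riddled with technical zeros ("dropout"). `pathimpute`
predicts the missing values reference-free — no matched scRNA-seq — by
exploiting two biological regularities at once:

1. **Spatial smoothness.** Neighboring cells influence each other through
   short-range cell-to-cell interactions, so expression varies smoothly
   across the tissue.
2. **Cell-type signatures.** Cells of the same type share expression
   programs even when they sit far apart (long-range, e.g. paracrine or
   endocrine, signaling notwithstanding).

Accuracy is scored by a masking protocol: 10% of the *nonzero* entries of
the ground-truth matrix are hidden as a test set and another 10% as a
validation set (`make_masks`), the model trains on the remainder, and the
held-out entries are compared with the truth by mean L1 distance, cosine
similarity and RMSE (`compute_metrics`). Masks are drawn uniformly over
nonzero entries without replacement; sizes are `round(frac * Z)` with
half-ties rounded down, and the three sets exactly partition the nonzero
set.

## The heterogeneous graph

Two undirected edge sets over the same n cells (`build_hetero_graph`):

* **Spatial graph** `G_s`: an edge joins cells whose Euclidean distance is
  at most `d_thr`. When `d_thr` is not supplied it is chosen as the
  smallest pairwise distance that brings the mean degree to 6, the
  hexagonal-lattice neighbor count of Visium arrays.
* **Expression graph** `G_g`: each cell selects its `knn_k` nearest cells
  by Euclidean distance on the highly-variable-gene (HVG) expression
  vectors (`select_hvg`, default 3100 genes ranked by a variance/mean
  dispersion on library-normalized counts). The directed top-k relation is
  symmetrized into an undirected edge set — walks must be able to traverse
  edges in both directions — and the directed lists are kept as a
  diagnostic attribute. Distance ties break by ascending cell index so
  builds are deterministic.

## Walks and path operators

Rather than averaging neighbors with a normalized Laplacian — which makes
deep stacks collapse all embeddings together (over-smoothing) — the model
convolves embeddings along *sampled paths*. From every node, `T` walks of
fixed node-length `k` are drawn on each graph with second-order
(Node2Vec) transition weights: from the current node, an unnormalized
weight `1/p` to return to the previous node, `1` to move to a common
neighbor of the previous node, and `1/q` to move outward; the first hop
is uniform. `k` counts *nodes*, so a length-8 path makes 7 hops, and an
L-layer model reaches `(k - 1) * L` hops. Position 1 of every walk is the
start node itself, so each node always contributes its own embedding.
Isolated nodes self-pad (repeat themselves), keeping the walk array
rectangular. Walks are resampled every training epoch through a
deterministic seed schedule (`resample_schedule`), so a run is fully
reproducible from one seed while never reusing paths; within an epoch the
per-graph walk set is shared across layers.

A **path operator** holds one learnable weight per path position and
channel. Writing `P = (v_1, ..., v_k)` for a walk and `f` for the n x d
embedding matrix, the convolved embedding of start node `v` is

    out(v)[j] = (1/T) * sum_{walks P from v} sum_{i=1..k} op[i, j] * f(v_i)[j]

i.e. a channel-wise multiply-accumulate along the path, averaged over the
`T` walks. (The operator algebra is defined per channel; collapsing the
channel sum into a scalar would be inconsistent with the d-dimensional
embedding each layer must produce, and with channel-distinct operator
variants.) Each layer convolves on both graphs, concatenates the two
results and applies a learned affine map with ReLU:

    f^(l+1) = relu(W1^(l) [op_s(P_s) * f^(l), op_g(P_g) * f^(l)] + b)

Four operator-sharing modes trade parameters for flexibility: `op_glo`
(one k-vector shared by all layers and channels), `op_cha` (per-layer
k-vectors), `op_lay` (one k x d matrix shared by all layers), `op_ind`
(per-layer k x d matrices; the default). Channel-distinct modes add
`(k_s + k_g) * d_emb` operator weights per layer — 1024 at the defaults
k = 8, d_emb = 64 — small next to the `2 d^2` combine weights, so the
model stays in the same parameter class as an ordinary GCN
(`count_parameters` gives the exact breakdown).

## Encoder, decoder, loss

Embeddings start from the observed expression. Because m is much larger
than the embedding width, a learned linear encoder maps the m observed
genes to `d_emb` dimensions before layer 1, and after layer L a decoder
maps back to gene space. The decoder is a one-hidden-layer perceptron
(width `d_emb`, ReLU); deeper decoders bought nothing in development, so
depth one is the default resolution of that open choice. A config switch
(`model.raw_features`) instead runs the literal reading where the
embedding *is* the expression vector (width m, no encoder/decoder).

The loss is the mean squared error over the *training* nonzero entries
only; validation RMSE is tracked on the validation entries, and training
stops when it has not improved for `patience` (default 50) consecutive
epochs, restoring the best-validation weights. Test entries are zeroed in
the input and excluded from every loss, and the suite asserts bit-equal
training trajectories when test values are perturbed.

Two initialization choices matter and are deliberate:

* the decoder output bias starts at the per-gene observed means, so early
  epochs do not have to learn gene abundances entry by entry;
* the decoder output *weights* start near zero (a 0.05-scaled fan-in
  init). At a plain random init the structural path injects noise around
  the already-good bias solution; the fastest descent direction is then
  to silence that path through the ReLUs, and runs stall in a dead
  plateau. Starting the output layer near zero lets structure grow only
  where it reduces the loss. The GCN baseline gets the identical
  treatment, so comparisons are about aggregation, not initialization.
* operator weights start from a normalized, geometrically decaying
  position profile (decay 0.7, jittered), so the initial convolution
  approximates a *local* neighborhood mean at any path length. A flat
  `1/k` start makes long paths begin as near-global averages — an
  over-smoothed input from which training reliably stalls.

Optimization is full-batch Adam (lr 1e-3 at production scale, weight
decay 1e-5) — dataset sizes of a few thousand cells do not need
mini-batching. Training and metrics operate on log-normalized values
(library-size scaling to 1e4 then `log1p`, the dominant convention;
per-entry errors ~0.3 on real data are only plausible on that scale);
normalization precedes masking, and since it preserves zeros exactly, the
mask set is identical on both scales.

## The synthetic generator

`simulate_spatial` produces datasets with known truth exhibiting exactly
the two structures above. Cells sit on a pitch-1 hexagonal lattice split
into `n_layers` contiguous horizontal bands (a layered-cortex cartoon).
Each band has a *dominant* cell type, but every cell re-draws its type
with probability `1 - type_mix` (default 0.4) from all types, so each
type also recurs scattered across the tissue — this is the regime the
expression graph exists for: faraway same-type cells. Every gene marks
one type (block-structured programs, random amplitudes, plus a low-rank
shared component), a smooth field adds two low-frequency plane waves per
gene, and Gaussian noise perturbs the log-rate. Counts are Poisson with
rate `base_rate * softplus(eta)` and zeros are inflated by independent
Bernoulli dropout, giving a closed-form expected observed density
`mean((1 - dropout) * (1 - exp(-rate)))` that the tests check against
the realized density.

Defaults (`base_rate = 3`, `dropout_rate = 0.7`, type scale 2.5, spatial
scale 1.5) put the layered fixture at ~0.26 observed density — the
filtered-data regime of the platforms this method targets — with counts
large enough that an observed value carries information about its rate.
At much lower rates nearly every observed count is 1 and *no* method can
beat per-gene means on held-out nonzeros; the generator deliberately
avoids that uninformative regime. What the generator does **not**
emulate: spot mixing, segmentation artifacts, batch effects, platform-
specific noise. Passing tests show the machinery works where its
assumptions hold, not that it wins on any particular real dataset.

Fixtures: `tiny` (30 x 20, unit tests), `layered` (500 x 200, both
signals), `smooth_only` (300 x 120, smooth field only), `type_only`
(300 x 120, type programs only with coordinates scrambled post hoc, so
the spatial graph is pure noise while expression marginals are
untouched).

## Desk-scale studies

The experiment harness re-runs the method's internal studies on the
fixtures at desk scale: embedding width 16, T = 2 walks (T = 4 in the
receptive-field sweep, where long paths need the extra averaging),
2 layers, Adam lr 1e-2, at most 300 epochs with patience 40, 5 replicate
seeds (masks, init, walks; the fixture itself is held fixed). These sizes are chosen so
the full suite trains ~90 small models in minutes; trends, not absolute
errors, are the object.

* **Receptive field** (`receptive_field_sweep`): the GCN baseline — mean
  aggregation with `D^-1/2 (A + I) D^-1/2` on the *union* of both edge
  sets, same masked loss, early stopping and initialization — is run at
  depths 2, 8, 32 against the path model at matched reach
  `R = (k - 1) * L` (L = 2, k = R/2 + 1). The GCN's error rises with
  depth while the path model stays flat; its embedding dispersion
  (variance across nodes over mean squared magnitude) collapses with
  depth, the over-smoothing signature.
* **Modality ablation** (`modality_ablation`): `var_s` feeds the layer
  combine the spatial convolution twice, `var_g` the expression
  convolution twice, `var_h` both. On `smooth_only` the spatial variant
  wins, on `type_only` the expression variant wins, and on `layered` the
  heterogeneous model matches or beats the best single modality.
* **Operator sharing** (`operator_ablation`): all four modes under an
  identical protocol; channel-distinct operators (`op_ind`) beat the
  fully shared `op_glo`, and parameter counts order
  `op_glo <= op_cha <= op_lay <= op_ind`.

All variants inside one comparison share fixture, masks and seeds,
asserted by input fingerprints carried in every `sweep_result`.

## Numerical and degenerate-input choices

* Mask rounding: `round(frac * Z)` with half-ties down; the three sets
  always partition the nonzeros exactly.
* All-zero cells pass through normalization untouched, with a warning.
* k-NN and threshold graphs are exact (no approximate index) — exactness
  at n <= 1e4 is the contract, and brute-force oracles pin it in tests.
* Dead ends and isolated nodes self-pad rather than restarting, keeping
  operator shapes fixed.
* The return bias p is not part of the reference parameterization; it
  defaults to 1 and is exposed for completeness.
* Gradients are analytic (hand-derived backprop through the path
  convolution, verified against central finite differences to 1e-4
  relative); the walk sampler uses its own deterministic RNG so runs are
  bit-reproducible from one seed.

## Limitations

Inference is transductive: the model imputes the cells it was trained on
and does not embed unseen cells. Only 2-D coordinates are supported. The
gene graph is rebuilt from the *observed* (masked) matrix, so extremely
sparse inputs degrade its quality before the model ever sees them — the
modality ablation quantifies how much that costs. Wall-clock performance
is adequate for a few thousand cells full-batch; nothing here is tuned
for atlas-scale data.
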