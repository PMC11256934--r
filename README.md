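# pathimpute

Reference-free imputation of dropout zeros in spatial transcriptomic
count matrices with a path-based heterogeneous graph neural network.

Spatial platforms (10x Visium, Stereo-seq, Slide-seqV2, ...) measure a
sparse cells x genes count matrix `X_obs` plus per-cell 2-D coordinates
`C`, with most entries lost to technical dropout. `pathimpute` predicts
the missing values without any matched scRNA-seq reference by combining
two complementary cell graphs:

* a **spatial graph** `G_s` linking cells within a Euclidean distance
  threshold (short-range cell-to-cell interaction), and
* an **expression graph** `G_g` linking each cell to its k nearest cells
  on highly-variable-gene expression (faraway cells of the same type).

Instead of Laplacian neighbor averaging — which over-smooths as layers
stack — node embeddings are convolved along second-order (Node2Vec)
random walks with a learnable **path operator**: one weight per walk
position and channel,

    out(v)[j] = (1/T) * sum_{walks P from v} sum_{i=1..k} op[i,j] * f(P_i)[j]

so a single layer reaches `k - 1` hops. Each layer concatenates the
spatial and expression convolutions and applies a learned affine map with
ReLU; a linear encoder and a one-hidden-layer decoder map between gene
space and the embedding space. Training minimizes the masked MSE over
observed nonzero entries (10% held out for testing, 10% for validation)
with Adam and early stopping on validation RMSE; held-out entries are
scored by mean L1 distance, cosine similarity and RMSE.

The package also ships a synthetic layered-tissue generator with known
ground truth (spatially smooth fields + scattered cell-type programs +
zero-inflated Poisson counts), a mean-aggregation GCN baseline, and
desk-scale reproductions of the method's internal studies
(receptive-field/over-smoothing, graph-modality ablation,
operator-sharing ablation).

## Worked example

```r
library(pathimpute)

sim   <- make_fixture("layered", seed = 1)     # 500 cells x 200 genes
norm  <- normalize_counts(sim$dataset)          # library-size + log1p
split <- make_masks(norm, seed = 1)             # 10% test / 10% val
obs   <- apply_mask(norm, split)

het <- build_hetero_graph(obs, hvg = select_hvg(norm, 100), knn_k = 10)
fit <- train_model(norm, split, het,
                   model_config(L = 2, d_emb = 16, k_s = 4, k_g = 4,
                                T_s = 2, T_g = 2),
                   train_config(max_epochs = 300, patience = 40,
                                lr = 1e-2, seed = 1))
X_hat <- impute(fit$model, obs$values, het, seed = 1)
evaluate_imputation(X_hat, norm, split)
#> metric_report (N=2573): L1 0.5512, cosine 0.9911, RMSE 0.6669
evaluate_imputation(column_mean_baseline(obs$values), norm, split)
#> metric_report (N=2573): L1 0.6744, cosine 0.9871, RMSE 0.8044
```

The trained model recovers the 2573 held-out test entries (10% of the
observed nonzeros) with ~17% lower RMSE than
per-gene mean imputation on this fixture; `fit$report` holds the
per-epoch training loss and validation RMSE with the best epoch marked.
`count_parameters(model_config(), m)` prints the exact parameter
breakdown — with the reference defaults (k = 8 on both graphs,
d_emb = 64) the operators add 1024 weights per layer, small next to the
combine maps.

A thin CLI wraps the same functions:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "pathimpute", package = "pathimpute"))')
Rscript $cli simulate --fixture layered --out sim/
Rscript $cli train --counts sim/counts.mtx --coords sim/coords.csv \
    --out run/ model.d_emb=32 seed=7
Rscript $cli evaluate --pred run/imputed.mtx \
    --truth sim/counts.mtx --mask run/masks.json
Rscript $cli experiment modality --fixture layered --out abl/
```

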