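# ddfusion

Disentangled dense fusion of multimodal embeddings, in R.

## What this is for

Multimodal prediction problems — a retinal image plus patient metadata, a
satellite image plus internet-activity and census signals — usually arrive
as *embedding tables*: one row per sample, one block of numeric columns per
modality, and a label. Concatenating the blocks and fitting one model wastes
capacity on *inter-modal redundancy*: the information the modalities share
is duplicated, and each block's private noise comes along with it.

`ddfusion` implements a fusion architecture that separates the two kinds of
information and penalises their overlap:

- a **Kronecker joint interaction** `C = A ⊗ B` (row-wise outer product)
  capturing all pairwise cross-modal feature interactions;
- **self-attention** per modality producing modality-specific features
  `Sa`, `Sb`, and **cross-attention** over the joint interaction (queries
  from `C`; keys/values summed from `C`-, `A`- and `B`-derived projections)
  producing modality-common features `Sc`;
- a **vCLUB mutual-information penalty** — the variational contrastive
  log-ratio upper bound
  `(1/N²) Σᵢ Σⱼ [log q(bᵢ|aᵢ) − log q(bⱼ|aᵢ)]` with a learned Gaussian
  approximator `q` — minimised between `concat(Sa, Sb)` and `Sc` so the
  common and specific parts stay disentangled;
- a **dense skip-connected head**: `h_final = concat(f_a(Sa), Sc, f_b(Sb))`
  feeding a dense prediction block, trained with
  `L = L_objective + λ · MI(concat(Sa,Sb), Sc)`, `λ ∈ [0,1]`.

Around the core: class-weighted focal loss (`α(c) = N/(K·N_c)`, focusing
parameter γ) for imbalanced labels, L2 weight decay, early stopping, a
sliding-window temporal variant for weekly grouped series (MSE objective,
chronological 80/20 split), a VAE embedding extractor for small images, the
usual baselines (per-modality logistic regression and neural nets,
early-fusion concatenation models), evaluation metrics (accuracy, macro /
weighted F1, macro AUC, MAE, RMSE, sMAPE, R²), and a seeded synthetic
generator with controllable shared/specific latent structure so everything
is testable offline. All networks run on an internal reverse-mode
computational-graph engine over base-R matrices; fits are deterministic
given the config seed.

## A worked example

```r
library(ddfusion)

# two modalities, 16 dims each, sharing an 8-dim latent; 4 classes
spec <- synthetic_spec(n_samples = 2000, redundancy = 0.7, noise_sd = 1,
                       seed = 7)
tab <- generate_classification(spec)
tab
#> <embedding_table> 2000 samples, 2 modality blocks
#>   block 'A': 16 dims
#>   block 'B': 16 dims
#>   label: factor with levels c1, c2, c3, c4

cfg <- ddf_config(proj_dim = 32, head_dim = 64, tokens = 2,
                  learning_rate = 3e-3, dropout = 0.6, patience = 40,
                  max_epochs = 200, seed = 1)
fit <- ddf(tab, model = "disentangled", config = cfg)
fit
#> <ddf> disentangled (classification), 2000 samples
#>   epochs run: 120, best epoch: 80
#>   residual vCLUB MI(concat(Sa,Sb); Sc): 243.7593 nats
#>   held-out test metrics:
#>     accuracy: 0.5710
#>     f1_macro: 0.5617
#>     f1_weighted: 0.5690
#>     auc_macro: 0.7922
```

The model trained for 120 epochs, early-stopped 40 epochs after its best
validation loss (epoch 80), and classifies 57% of held-out samples correctly
on a 4-class task whose attainable accuracy is limited by the generator's
noise. Training the same network with `model = "dense_fusion"` (identical
architecture, `λ = 0`) reaches a comparable macro-F1 (0.573) but leaves the
residual mutual information between the specific and common features at 802
nats versus 244 — the disentanglement penalty is doing its job. `predict()`, `summary()`
and `plot()` (training curves) work as for any fitted model.

For weekly grouped series:

```r
ttab <- generate_temporal(synthetic_spec(seed = 3), n_groups = 10,
                          n_weeks = 260, ar_coefficient = 0.8)
ws <- make_windows(ttab, temporal_window_spec(window = 3, horizon = 1))
tfit <- ddf_temporal(ws, ddf_config(task = "regression", proj_dim = 16,
                                    head_dim = 32, tokens = 2, seed = 1))
tfit$metrics$r2   # 0.17 > 0: beats the mean predictor on held-out future weeks
```

There is also a small command-line surface over the same functions:

```sh
Rscript inst/cli/ddf.R generate --task classification --n 1000 --seed 7 --out tab.csv
Rscript inst/cli/ddf.R train --table tab.csv --model disentangled --out-dir run/
Rscript inst/cli/ddf.R ablate --table tab.csv --models disentangled,dense_fusion,concat_mlp --out-dir abl/
```

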