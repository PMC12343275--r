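# cytoattn

Classification of acute promyelocytic leukemia (APL) fusion-gene subtypes
— PML-RARA, TTMV-RARA, NPM1-RARA, STAT5B-RARA, NUP98-RARG — from
single-cell bone marrow smear images, with pixel-level visualization of
*where* the model looked. The five subtypes respond differently to
differentiation therapy but are nearly indistinguishable by eye, and
genetic confirmation takes weeks; a morphology-based classifier with
interpretable attention is the use case this package serves.

The package is aimed at computational pathology researchers who want a
fully inspectable, dependency-light reference implementation: every layer
of the network — and its backward pass — is plain R plus two small
C++ convolution kernels, with no deep-learning framework.

## The model

A residual CNN with an explicit spatial attention module:

* stem 3×3 conv (3→32) + batch norm + ReLU, stride 2;
* three residual stages (32, 64, 128 channels; additive shortcuts, 1×1
  projection on shape change; stride 2 at stages 2–3);
* after stage 1, a **spatial attention module**: a 1×1 convolution
  compresses the feature map X to one channel M, a sigmoid maps it to the
  attention map A ∈ (0,1), and features are reweighted elementwise,
  `Y[k,i,j] = X[k,i,j] · A[i,j]`;
* global average pooling + fully connected head, softmax probabilities;
* training: cross-entropy, Adam, learning rate halved every 10 epochs,
  seeded 50/50 stratified split and shuffling.

Evaluation reports the confusion matrix, per-class precision / recall /
F1 with **Wilson score 95% confidence intervals**, overall accuracy with
CI, and one-vs-rest ROC/AUC. Visualization upsamples A to image
resolution, normalizes, colors (blue → cyan → green → yellow → red) and
alpha-blends it over the cell; Grad-CAM provides the analogous map for
the two bundled comparison architectures (a QKV self-attention residual
net and a plain multi-layer CNN).

Because the study's real smears are private, the package includes a
seeded synthetic single-cell smear generator (five visually separable
class recipes; nucleus shape/size/hue, granularity, Auer-rod-like
inclusions for the PML-RARA-like class) with pixel-level ground-truth
masks, so the whole pipeline is testable offline.

## Worked example

```r
library(cytoattn)

# five-class synthetic dataset at reduced scale (majority class capped)
spec <- dataset_spec(per_class_counts = c("PML-RARA" = 200L, "TTMV-RARA" = 98L,
                                          "NPM1-RARA" = 58L, "STAT5B-RARA" = 38L,
                                          "NUP98-RARG" = 12L),
                     master_seed = 424242L)
ds <- generate_dataset(spec)
class_separability_check(ds)
#> [1] 0.9901478

sp  <- stratified_split(ds$manifest, 0.5, seed = 99L)
tr  <- match(sp$train$path, ds$manifest$path)
te  <- match(sp$test$path,  ds$manifest$path)

cfg   <- arch_config(class_names = names(spec$per_class_counts))
model <- build_model(cfg, seed = 1L)
model <- train_model(model, ds$samples[tr], config = train_config(epochs = 30L, seed = 7L))

evaluate_model(model, ds$samples[te])
#> <eval_report>  n = 203,  accuracy 1.0000 (95% CI 0.981, 1.000)
#>   PML-RARA     P 1.000 (0.963, 1.000)  R 1.000 (0.963, 1.000)  F1 1.000  AUC 1.000
#>   TTMV-RARA    P 1.000 (0.927, 1.000)  R 1.000 (0.927, 1.000)  F1 1.000  AUC 1.000
#>   NPM1-RARA    P 1.000 (0.883, 1.000)  R 1.000 (0.883, 1.000)  F1 1.000  AUC 1.000
#>   STAT5B-RARA  P 1.000 (0.832, 1.000)  R 1.000 (0.832, 1.000)  F1 1.000  AUC 1.000
#>   NUP98-RARG   P 1.000 (0.610, 1.000)  R 1.000 (0.610, 1.000)  F1 1.000  AUC 1.000
```

The separability line says a leave-one-out nearest-centroid classifier on
ten simple color/shape features already gets 99% of the synthetic images
right — the generator's classes carry real signal, so the CNN reaching
test accuracy 1.000 on the 203 held-out images is expected, and the wide
NUP98-RARG interval (n = 6) shows why every proportion here carries a
Wilson interval rather than a bare point estimate.

```r
ov <- attention_overlay(model, ds$samples[[te[1]]]$pixels)  # heatmap + composite
attention_figure(model, lapply(ds$samples[te[1:5]], `[[`, "pixels"),
                 "panels.png")                               # 3-row figure
```

A command-line wrapper with `generate` / `train` / `evaluate` /
`visualize` / `compare` subcommands is installed at
`inst/cli/cytoattn` (YAML-configured; see `--help`-style usage in the
script header).

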