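# rbpnn — prototype-embedded radial basis probabilistic neural networks

`rbpnn` classifies 2-D images whose classes are internally heterogeneous —
"one disease, multiple symptoms": a single diagnostic label covering several
visually distinct presentations, small low-contrast targets, low
signal-to-noise. Standard softmax classifiers model each class as one convex
region; this package instead embeds *several prototype features per class* as
fixed kernel centers of a radial basis probabilistic neural network (RBPNN),
so a class decision region is the union of its subclass neighborhoods and may
be non-convex. It is aimed at small labeled image sets (hundreds of samples
per class) where that structural constraint matters, e.g. medical image
triage.

## The method

1. **Feature extraction.** A ResNet-style convolutional stack with
   feature-pyramid fusion (top-down, lateral 1×1 connections), a pyramid
   pooling module (grids 1, 2, 3, 6), and mixed spatial/channel self-attention
   (residual gates δ, ε initialized to 0) produces, per image, a
   *comprehensive feature matrix* F ∈ R^(n×L): rows are channels, columns a
   pooled spatial profile.

2. **Channel cosine-similarity attention (CSA).** For feature matrices X, Z
   the per-channel cosine similarities, the channel similarity profile `M_C`
   (row-normalized C×C cosine matrix), and average-pooled channel weights
   `A_C` define the distance

       d(X, Z) = Σ_c w_c (1 − cos(X_c, Z_c)),   w_c ∝ M_C[c]·A_C[c] of Z,

   bounded in [0, 2] and invariant to per-row positive rescaling.

3. **Dynamic C-means (DCM) prototype selection.** Per class, sample densities
   D_i = Σ_k 1/(1 + f_d d²(X_i, X_k)) seed a farthest-point initialization;
   medoid refinement keeps centers at actual training samples ("typical
   features"); the validity index GD(c) = α·C_d(c) + (1−α)/S_d(c) (coupling =
   mean squared within-cluster distance, separation = mean squared
   between-center distance) picks the subclass count c.

4. **RBPNN head.** Each prototype z_kl becomes a frozen kernel center with
   activation h_kl = 1/(1 + exp(a·d²/σ_k² − c)); the pattern aggregation
   layer sums activations by class, q_k = Σ_{j∈Ω_k} h_j; a softmax layer on q
   yields class probabilities. Mini-batch gradient descent (cross-entropy,
   lr 0.01, batch 10) trains the softmax weights and the kernel smoothing
   parameters; centers never move.

A synthetic-data module generates image sets with planted multi-subclass
structure (per-subclass blob motifs, jitter, additive noise) and labeled
feature-matrix mixtures, so the whole pipeline is testable without any
external download.

## Worked example

```r
library(rbpnn)

# 4 classes x 3 visual sub-modes, 32x32 grayscale, 67 images per sub-mode
full <- generate_image_set(synthetic_spec(
  n_classes = 4, subclasses_per_class = 3, samples_per_subclass = 67,
  image_size = 32, seed = 101))
sp <- split_image_set(full, train_per_subclass = 50)   # 600 train / 204 test

model <- rbpnn_fit(sp$train$images, sp$train$class_labels,
                   rbpnn_pipeline_config(seed = 1))
model
#> Prototype-embedded RBPNN classifier
#>   classes: 4 | prototypes per class: 2, 3, 5, 4
#>   kernel: a = 1.869 c = 4.118 | sigma = 0.02883, 0.02901, 0.03128, 0.02882
#>   training: 20 epochs, final loss 0.4919, accuracy 0.952

m <- rbpnn_evaluate(model, sp$test$images, sp$test$class_labels)
round(c(accuracy = m$accuracy, f1 = m$f1), 3)
#> accuracy       f1
#>    0.946    0.946
```

The printout reads: dynamic C-means found 2–5 subclass prototypes per class
(3 were planted; close neighbors in feature space are sometimes merged or
split), the kernel transition was calibrated at a = 1.87, c = 4.12 from the
training margins, and the frozen-extractor model reaches 94.6% held-out
accuracy against a 25% chance level. Predictions for new images come from
`predict(model, images)` (class probabilities, pattern responses and RBPN
activations).

A thin command line sits over the same functions:

```sh
Rscript inst/cli/rbpnn-cli.R train --config cfg.yaml --seed 1 --model model.rds
Rscript inst/cli/rbpnn-cli.R evaluate --model model.rds --manifest test/manifest.csv --out metrics.json
```

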