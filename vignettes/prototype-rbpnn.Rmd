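---
title: "Prototype-embedded RBPNN classification: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prototype-embedded RBPNN classification: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpnn)
```

## The problem and the model

Many image classification problems — medical imaging is the motivating case —
pair a single diagnostic label with several visually distinct presentations:
a class is a *mixture of sub-modes*, targets are small and low-contrast, and
labeled samples are scarce. A plain softmax head models each class as one
convex region of feature space and must either blur the sub-modes together or
spend scarce data learning to separate them implicitly.

`rbpnn` makes the sub-mode structure explicit. The model has four stages:

1. **Multi-scale feature extraction.** A ResNet-style stage stack (each stage
   a 3×3 stride-2 halving convolution plus a residual basic block) feeds a
   feature pyramid: lateral 1×1 connections project every stage to a common
   width and a top-down pass adds each bilinearly upsampled coarser level to
   the next finer one. A pyramid pooling module (grids 1, 2, 3, 6 by default)
   attaches global context to the finest fused level, and a mixed attention
   block — spatial attention over all position pairs, channel attention over
   all channel pairs, each gated by a residual scale initialized to exactly
   zero — produces the enhanced map. Adaptive average pooling to a
   `profile_grid × profile_grid` spatial profile and row-major flattening
   yield the *comprehensive feature matrix* `F` (rows = channels, columns =
   `L = grid²` profile positions) on which everything downstream operates.

2. **Channel cosine-similarity attention (CSA).** The similarity of two
   feature matrices is judged channel-wise by cosine, weighted by how
   important each channel is *to the reference (prototype) side*: the weight
   of channel `c` is proportional to the product of the prototype's mean
   channel similarity `M_C[c]` (row means of the shifted, row-normalized
   cosine matrix of its channels) and its average-pooled activation `A_C[c]`,
   clamped at zero and renormalized. The resulting distance
   `d = Σ_c w_c (1 − cos(F_c, Z_c))` lies in `[0, 2]`, vanishes exactly when
   every channel pair is positively collinear, and ignores per-channel
   positive rescaling.

3. **Dynamic C-means (DCM) prototype selection.** Within each class, sample
   densities `D_i = Σ_k 1/(1 + f_d d²_ik)` (with `f_d = 4/r_d²` and `r_d`
   half the root-mean-square pairwise distance) rank the points; seeds are
   the density peak followed by farthest-point picks among points at or above
   half the maximum density; medoid refinement alternates nearest-center
   assignment with a medoid update, so centers remain actual training
   samples. The cluster count is chosen by the validity index
   `GD(c) = α·C_d(c) + (1 − α)/S_d(c)` — coupling `C_d` is the mean squared
   sample-to-center distance, separation `S_d` the mean squared
   center-to-center distance — evaluated over a candidate range, smallest
   `GD` wins, ties to the smaller count.

4. **RBPNN head.** The selected medoid features become frozen kernel centers
   `z_kl`. A radial basis probabilistic neuron responds with the exponential
   sigmoid `h_kl = 1/(1 + exp(a·d²/σ_k² − c))`; the pattern aggregation layer
   sums responses by class (`q_k = Σ_{j∈Ω_k} h_j`), merging subclass
   neighborhoods into one — possibly non-convex — class region; and a softmax
   layer on `q` yields probabilities, argmax (ties to the smallest index)
   the label. Mini-batch gradient descent on cross-entropy updates the
   softmax weights `θ` and, by default, the smoothing parameters `a` and `c`;
   the centers and the feature extractor stay frozen.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `stage_channels` (tiny) | 16, 32, 64, 128 | channel widths of the four halving stages at 32×32 input |
| `fpn_channels` | 32 (tiny) / 256 (standard) | uniform width of the fused pyramid |
| `ppm_scales` | 1, 2, 3, 6 | pooled grid sizes of the pyramid pooling module |
| `profile_grid` | 4 (tiny) / 7 (standard) | spatial profile of the feature matrix; `L = grid²` |
| `alpha` | 0.8 | coupling weight of `GD(c)` (see below) |
| `keep_rule` | 0.5 | density fraction below which points are excluded from seeding |
| `c_range` | `2:min(10, N/2)` | candidate subclass counts per class |
| `a`, `c_smooth` | calibrated | kernel slope and offset (sigmoid transition) |
| `sigma_k` | estimated | per-class kernel width, RMS nearest-center distance |
| `learning_rate`, `batch_size`, `max_epochs`, `error_tolerance` | 0.01, 10, 20, 0.05 | mini-batch gradient descent settings |

The defaults fit the desk-scale `tiny` variant (grayscale 32×32). The
`standard` variant mirrors a 224×224, five-stage, 3-channel front end; it
shares every code path and is configuration, not separate machinery.

## Initialization of the frozen extractor

The default training regime extracts features with the *initialized* backbone
and freezes it; only head-side parameters learn. Two consequences drove the
initialization design, both extensions of the attention gates' own
start-at-zero device:

* **Identity-preserving fusion.** With plain He initialization, the random
  channel mixes in the FPN laterals, the PPM fusion convolution, and the
  attention aggregation head scramble exactly the channel-direction structure
  the CSA metric reads (measured on the synthetic benchmark: nearest-neighbor
  subclass purity of the extracted features fell from ~0.98 to ~0.72, with
  large variance across initialization seeds). All fusion convolutions
  therefore initialize as exact identities (or deterministic channel
  replication/group-averaging where widths differ), every residual branch
  starts at zero, and randomness remains only in the stage convolutions.
  A trained deployment is free to move all of these weights.

* **Dataset-statistics normalization.** Inputs are resized and normalized by
  per-channel mean and standard deviation computed from the training images
  (stored in the fitted model); explicit values — e.g. the familiar ImageNet
  constants, which are themselves dataset statistics — can be passed instead.
  A fixed mid-range normalization leaves the (large, shared) background
  response dominating every channel, and cosine-based distances collapse.

## Numerical choices

* **Kernel form.** The kernel argument is the *squared* CSA distance over the
  squared class width, `a·d²/σ_k² − c`: the standard radial-basis scaling,
  self-normalizing at the class's own distance scale. (Scaling `d` rather
  than `d²` by `σ²` makes the argument grow like `1/d` for small distances
  and saturates every activation; the non-convexity property below fails
  under that reading.)
* **Kernel calibration.** `a` and `c` initialize so the sigmoid's transition
  sits midway between the median exponent to the nearest same-class center
  and the median exponent to the nearest other-class center (`calibrate_kernel`);
  a typical same-class query then activates near 0.88 and a cross-class query
  near 0.12. Without this bandwidth-style initialization all activations live
  in the sigmoid's exponential tail, where a class with several moderately
  distant centers outsums the correct class's single near center and
  gradients vanish. Both parameters remain trainable.
* **Scale-free validity index.** `C_d` and `1/S_d` carry units of `d²` and
  `d⁻²`, so the raw index's balance depends on the absolute distance scale —
  on extracted image features (distances ~0.05) the separation term is five
  orders of magnitude larger. Each class's distance matrix is rescaled to
  unit RMS before the index is evaluated; density, seeding and medoid
  refinement are invariant to this rescaling.
* **Coupling weight α = 0.8.** Prototype selection has asymmetric costs:
  under-segmentation leaves a sub-mode with no kernel center — invisible to
  the RBPN layer — while over-segmentation only adds redundant centers.
  Weighting compactness above separation encodes that asymmetry.
* **Density pruning.** Seeding excludes points below half the *maximum*
  density rather than below a density quantile: isolated outliers score near
  1 while mode members score near `N`, so the value-based rule removes
  genuinely sparse points but can never delete an entire uniform-density
  mode (a rank-based rule can, and then no seed may reach that mode).
* **Conventions.** One reshape dialect everywhere: spatial positions flatten
  row-major (`p = (i−1)·W + j`); bilinear interpolation uses half-pixel
  centers; softmax rows are stabilized by max subtraction; distance and
  argmax ties break toward the lowest index; the directed CSA distance
  (weights from the reference side) is symmetrized by averaging the two
  directions only where a center-pair distance is needed (separation degree).
* **Degenerate inputs.** Zero vectors have cosine 0 by convention (with a
  warning); coincident samples give the density limit `D_i = N`; an emptied
  cluster is re-seeded with the farthest point; `σ_k` is floored at `1e-6`;
  `S_d = 0` maps to `GD = ∞` so coincident centers are never selected.

## What the synthetic data does and does not show

`generate_image_set` plants exactly the structure the method claims to
exploit: each (class, subclass) pair is a motif of 1–3 Gaussian blobs
(radius 2–5 px, amplitude 0.35–0.65 over a 0.1 background) with per-sample
position/radius/amplitude jitter and additive pixel noise (σ = 0.1), clipped
to `[0, 1]`. `generate_feature_set` plants cluster means with sparse
non-negative channel profiles on (near-)disjoint supports — the feature-space
analogue of distinct sub-modes exciting distinct units — rescaled so the
planted means satisfy a minimum Euclidean separation, plus isotropic noise.

Passing tests on these sets shows the pipeline recovers planted multi-modal
structure and classifies far above chance under low SNR with a frozen
extractor. It does not show performance on real clinical images: real
sub-modes are not Gaussian blobs, class boundaries are not noise-limited in
the same way, and a trained (or pretrained) backbone would change the feature
geometry substantially. Subclass ground truth is carried only for evaluation;
no training path reads it.

Problem sizes used throughout the tests and the acceptance script — 600
training / 204 test images at 32×32 with the tiny backbone, 30 samples per
planted cluster for the validity-index experiments, 160/160 samples for the
XOR contrast — were chosen as the smallest sets on which the studied effects
are stable.

## Design choices where the design was open

* **Where attention and pooling sit.** The pyramid pooling module and the
  mixed attention block operate on the *finest* fused pyramid level, which
  carries both detail and (through the top-down pathway) deep semantics; the
  coarsest level of a 32×32 tiny model is 2×2 and cannot support either
  spatial attention or a 6×6 pooling grid.
* **Frozen extractor.** Whether the convolutional front end should be trained
  through the RBPN layer is genuinely open; this package implements the
  frozen regime (features extracted once, head-side parameters trained),
  which keeps the prototype semantics intact — centers are features of real
  training samples in the same space as every query. The attention gates
  δ and ε consequently stay at their zero initialization.
* **Hard memberships.** The coupling degree is computed with hard (0/1)
  memberships; no fuzzifier is introduced. Medoid (not mean) center updates
  keep centers at actual samples, which the kernel-center role requires.
* **Pruned points re-enter.** Density pruning affects seeding only; every
  sample takes part in assignment, refinement and the validity index.
* **Aggregation head width.** The 1×1 convolution closing the attention block
  preserves the channel count by default (configurable).
* **XOR contrast protocol.** The two-prototype versus one-prototype
  comparison fixes the kernel at its reference parameters (`a = 1`, `c = 0`)
  for both variants, so the contrast isolates the effect of prototype count
  rather than of kernel calibration (which partially compensates for a
  missing prototype by widening the surviving one).

## Known limitations

* The validity index cannot signal "no substructure": on a homogeneous class
  it keeps preferring more clusters (a generic weakness of
  compactness/separation indices without a null reference), costing only
  redundant centers. Hierarchically spaced sub-modes (two close, one far) may
  be merged at the default α.
* The frozen random extractor sets the accuracy ceiling; nothing in the
  package backpropagates into convolutions.
* CSA weights assume predominantly non-negative channel activations
  (post-ReLU); features engineered to have negative row means degrade to
  uniform channel weighting.
* The exponential-sigmoid activations are probabilities only in the loose
  membership sense; `q_k` is a sum of bounded similarities, not a calibrated
  class posterior — calibration, if needed, must come from the softmax layer.
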