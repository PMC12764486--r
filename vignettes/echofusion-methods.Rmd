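---
title: "Masked video auto-encoding and spatio-temporal fusion for echocardiograms: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masked video auto-encoding and spatio-temporal fusion for echocardiograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package computes

`echofusion` implements a two-stage pipeline for learning from
echocardiogram video without frame-level annotation:

1. **Self-supervised pre-training.** A clip of `T` frames (each
   `3 x H x W`) is partitioned into non-overlapping space-time cubes of
   `tau x h x w` pixels; each cube is linearly projected to one token of
   width `d_model`, giving a sequence of length
   `L_seq = (T/tau) (H/h) (W/w)`. A fraction `rho` of tokens is hidden;
   only the visible ones pass through a deep transformer encoder with
   joint space-time attention, and a shallow decoder must reconstruct the
   pixels of the hidden cubes. The loss is the mean squared pixel error
   over masked cubes only,

   `L_recon = (1/|M|) * sum_{i in M} |V(i) - V_hat(i)|^2`,

   where `V(i)` are the pixels of cube `i` (per-cube means, so the loss
   equals the MSE over all masked-cube pixels). Because masked tokens
   never enter the encoder, encoder cost scales with `(1 - rho) L_seq`;
   at the default `rho = 0.85` only 15% of tokens are processed.

2. **Downstream transfer.** The decoder is discarded. For a labeled task
   (ejection-fraction regression, EF-threshold classification) the full
   unmasked token sequence is encoded and condensed into one clip vector
   either by mean pooling or by the **spatio-temporal fusion network
   (STF)**: a joint pathway (3D positional encodings, one 3D-convolutional
   residual block over the `t x h x w` token grid, gated attention
   pooling) concatenated with a disjoint pathway (per-slab 2D residual
   block, a large-kernel convolution with kernel = stride = grid extent
   acting as learnable pooling, sparse positional encodings built from the
   clip's original frame indices, gated attention pooling over the
   temporal slabs). The fused vector has width `2 d_model` and feeds a
   two-layer MLP head.

Gated attention pooling scores each instance vector `x_k` as
`w' (tanh(V x_k) * sigmoid(U x_k))` with `w in R^{L x 1}`,
`U, V in R^{L x d_model}`, `L = 1024`; the softmax of the scores gives
strictly positive weights summing to one, so the pooled vector lies in
the convex hull of its inputs and is invariant to instance order.

## Default parameters and where they come from

| parameter | default | note |
|---|---|---|
| input clip | `16 x 3 x 224 x 224` | reference configuration |
| cube strides `tau, h, w` | 2, 16, 16 | temporal stride deliberately finer than spatial |
| `d_model` | 768 | ViT-Base width |
| encoder / decoder depth | 12 / 4 | asymmetric design |
| heads, MLP ratio | 12, 4 | ViT-Base convention (not stated by the source; flagged) |
| decoder width | `d_model / 2` | our choice; source says only "shallow" |
| mask ratio `rho` | 0.85 | best value in the mask-ratio sweep {0.5 ... 0.9} |
| pre-training optimizer | AdamW, betas (0.9, 0.95), wd 0.05 | |
| learning rate | warmup 1e-5 to 1e-4 over first 5% of steps, cosine to 0 | cosine floor 0 is our choice |
| pre-training schedule | 30 epochs, batch 8 | |
| fine-tuning optimizer | AdamW, betas (0.9, 0.98), wd 1e-3 | 50 epochs, batch 16, best epoch by validation loss |
| EF thresholds | 0.50 / 0.45 | binary heart-function labels; positive class = preserved EF, boundary uses `>=` |
| volume labels | trained as `ln(y)` | predictions mapped back before scoring |

A `tiny` profile (`32 x 32` frames, `T = 8`, `d_model = 64`, depths 2/1,
gate width 64) exercises every code path on one CPU; all tests use it.

## The phantom generator: what it emulates, what it does not

No patient data ships with the package. `generate_phantom()` draws a
beating chamber: a dark ellipse (blood pool) inside brighter tissue,
clipped to an ultrasound scan sector, with multiplicative log-normal
speckle (`pixel * exp(sigma g)`, `g ~ N(0,1)`, clipped to `[0, 1]`). Both
semi-axes follow a raised cosine between end-diastole and end-systole
within each cardiac cycle; with fractional contraction `c` the
prolate-ellipsoid proxy `Vol ~ a b^2` gives exactly

`EF = 100 (1 - (1 - c)^3)`,

so every clip has an analytically known EF/ESV/EDV and regression on
clips is solvable in principle. Dataset defaults: contraction uniform in
(0.05, 0.35) (EF roughly 14-73%, spanning reduced to preserved
function), 24 raw frames, cycle length 12 frames (two cycles per clip at
a realistic frames-per-beat ratio), speckle sigma 0.15, 75-degree sector.

The phantom deliberately omits: point-spread functions and acoustic
shadowing, view variability, probe motion, valve and wall anatomy,
out-of-plane motion. A green test therefore establishes that the
*machinery* (tokenization, masking, optimization, fusion, metrics) works
end-to-end and that representations carry chamber-dynamics information --
it says nothing about clinical performance on real echocardiograms.

## Numerical and training choices

- **All gradients are hand-derived** (no autodiff exists in this R
  stack) and verified against central finite differences in
  `test-nn.R` at relative error < 1e-3; layer-norm and group-norm use
  epsilon 1e-5; GELU is the exact `x * pnorm(x)` form.
- **Target standardization.** Regression targets are z-scored on the
  train split inside the training loops and the transform inverted before
  any metric. At desk-scale step counts (hundreds of Adam steps, not the
  reference's hundreds of thousands) a zero-initialized head cannot reach
  raw-percent EF values; standardization removes that artifact without
  touching the reported raw-scale metrics. Volumes additionally use the
  log transform first.
- **Frozen-feature standardization in probes.** The encoder's final
  layer norm fixes per-token scale, leaving across-clip variance of
  pooled features near 0.005; both probing loops therefore z-score the
  frozen features on the train split (per channel for the STF probe).
  The stats are stored in the fitted object and applied at prediction.
- **Mask count** is `floor(rho * L_seq)`; masking is uniform over all
  space-time tokens.
- **Raster order** is fixed t-major (then h, then w) everywhere:
  tokenization, STF reshapes, and saliency maps share one bijection, so
  no reshape convention can drift.
- **3D positional encodings** split `d_model` into three near-equal even
  sinusoidal blocks (t/h/w); remainder channels are zero. The same
  factorized encoding (at decoder width) is added to the decoder input.
- **Sparse frame-index encodings** (disjoint pathway) average groups of
  `tau` consecutive sinusoidal encodings of the original frame indices --
  the pair-averaging described for `tau = 2`, generalized so any `tau`
  yields one encoding per temporal token.
- **Residual blocks** are three stacks of channel-preserving conv
  (3x3x3 or 3x3) -> group norm (8 groups when divisible) -> ReLU, with
  one additive skip around the stack: the smallest structure consistent
  with "convolution, activation, normalization, residual connection"
  stacks.
- **Rollout** uses the standard residual mixing `0.5 (A + I)` with row
  renormalization, head-averaged attention, and the grid-center token as
  the default query (a random query is irreproducible without a recorded
  seed; `random:<seed>` is available).
- **Ties and degenerate inputs.** `r2` errors on constant truth; AUC
  errors on single-class labels and averages tied ranks; EF-threshold
  boundary uses `>=` with positive = preserved function.

## Design decisions where the design was open

- The disjoint pathway's printed sizes reuse the symbols `h, w`; they are
  interpreted as the grid extents `H/h, W/w` (the only reading consistent
  with the reshape arithmetic).
- Both gated-attention pools share the same gate width `L`.
- Without STF, the clip representation is mean pooling over tokens.
- Multi-class AUC is macro one-vs-rest; F1 is positive-class (binary) or
  macro (multi-class). 95% CIs use a 1000-replicate nonparametric
  bootstrap over test clips.
- The encoder adds fixed sinusoidal positional encodings at its input
  (standard for masked auto-encoding; the source is silent on this
  point).
- The pre-trained-vs-random-init comparison in the acceptance suite runs
  in a low-labeled-data regime (25% of train labels, identical budgets
  in both arms). With full labels and saturating budgets the phantom task
  is easy enough that a randomly initialized encoder catches up; the
  limited-label setting is where the pre-training benefit is expressed,
  which matches the data-efficiency story the method tells at full scale.

## What the phantom cannot show

One acceptance contrast deliberately stays red: on phantom data the STF
network does not systematically beat mean pooling (it wins roughly half
the seeds under every protocol tried). The phantom's EF signal is global
-- chamber contraction modulates a large fraction of all pixels -- so
mean-pooled encoder features are already near-sufficient and STF's extra
capacity mostly adds optimization variance. The argument for fusion
(mean pooling dilutes spatially localized, positionally meaningful
signal) only has force at real-data scale with ~1500 tokens per clip; a
16-64 token phantom cannot express it. The pre-training benefit, by
contrast, reproduces cleanly in the limited-label regime.

## Known limitations

- Only uncompressed RGB24/8-bit AVI is decodable (no codec library is
  available in the target environment); files the package writes
  round-trip exactly and play in standard players.
- Training is single-threaded CPU R; the paper-profile configuration
  (768-wide, 12-layer, 224x224 input) constructs and runs forward passes
  but is not practical to train here -- all experiments use the tiny
  profile.
- The acceptance experiments are property-based contrasts on phantom
  data; none of the published clinical numbers are reproduced or
  asserted.
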