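---
title: "Strip-pooling feature fusion for brain-tumour MRI classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strip-pooling feature fusion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Multi-class brain-tumour classification from whole-brain MRI slices
(glioma / meningioma / pituitary adenoma / no tumour) is usually attacked
either with shallow VGG-style stacks, which capture fine local texture but
little context, or with deep residual networks, which capture context but
blur small-lesion detail. `stripfuse` implements a hybrid:

* a **shallow backbone** of three spatial blocks (3×3 convolution → batch
  normalisation → ReLU), the first two downsampling by 2×2 max pooling and
  2×2 average pooling respectively;
* a **deep backbone** of four residual blocks, each two 3×3 convolutions
  (the first followed by BN + ReLU, the second by ReLU only) plus a skip
  connection — identity where the block preserves shape, a strided 1×1
  projection elsewhere. Deep-layer downsampling uses strided convolutions,
  shallow-layer downsampling uses pooling;
* two **strip-pooling combination heads**, tapped after the third spatial
  block and after the fourth residual block. Each head computes per-row and
  per-column means of its feature map (strip pooling), pushes each
  descriptor through a channel-mixing 1-D convolution (kernel 3) and batch
  normalisation, broadcasts both back to the full spatial extent, sums
  them, and squeezes a sigmoid gate out of a 1×1 convolution. The gated map
  is globally average-pooled, dropout-regularised, and projected to a
  fixed-length vector by a fully connected layer;
* a **cross-scale fusion**: the shallow and deep head vectors (equal length
  `D`) are concatenated and fed to a single linear classifier with softmax.

Strip pooling aggregates along entire rows or columns, so the gate responds
to elongated, anisotropic structures — ragged, strip-like lesions — that
square pooling windows average away. That is the architectural hypothesis
the ablation variants (A–F) are designed to isolate: A/B test the shallow
head on a spatial-only backbone, C/D the deep head on a residual-only
backbone, E/F the full backbone without/with both heads.

## Choices the text of the design left open

Several details are not derivable from the architecture's verbal
description; the package fixes them as follows.

* **Same padding everywhere.** The convolution operator is defined in
  valid form (output `(M−r+1)×(N−s+1)`), but the stated block counts only
  produce sensible map sizes if backbone convolutions preserve spatial size
  except at pools and strides — the standard VGG/ResNet convention.
* **Residual branch ordering.** The second convolution is followed by ReLU
  and then the skip addition, with no post-addition activation. This makes
  a zero-weight block exactly the identity, which is pinned by a test.
  (The second convolution deliberately carries no batch normalisation; the
  description is explicit, though canonical ResNet differs.)
* **Strip-head normalisation** is batch normalisation per direction, as in
  the strip-pooling module this head descends from.
* **One fused gate.** The two directional maps are summed *before* the 1×1
  convolution and sigmoid, producing a single gate rather than separate
  height/width gates.
* **Side-branch heads.** The backbone feeds the third spatial block's raw
  output into the first residual block; the heads are taps, not in-path
  replacements.
* **Channel plan.** The architecture's width schedule is never printed;
  only the total — approximately 9.8 million trainable parameters — is.
  With spatial widths (32, 64, 128), residual widths (128, 192, 384, 512),
  strides (1, 2, 2, 2) and head dimension `D = 256`, the build comes to
  9,481,860 parameters, 3.2% under the printed figure and well inside the
  ±10% band the test suite enforces. Wider late-stage plans (e.g. a
  512→512 final block) overshoot the budget once the channel-mixing strip
  heads are costed honestly, which is why the fourth block widens only to
  512 from 384.
* **Batch-norm eps 1e-5, momentum 0.1; AdamW β = (0.9, 0.999), eps 1e-8** —
  ecosystem defaults, unstated in the protocol.
* **Sobel enhancement is additive** (`img + w·|∇img|`, clipped), with the
  magnitude from the standard 3×3 kernels and replicate padding; the
  protocol says the filter was "applied to sharpen", which does not decide
  between replacement and addition, and addition preserves the underlying
  anatomy.
* **Unsharp mask kernel.** The stated "100-pixel radius" is realised as a
  Gaussian with σ = radius/3, truncated at 3σ, reflecting boundaries — a
  common unsharp-mask convention; only the radius is stated.
* **Grayscale conversion** uses luminance weights (0.299, 0.587, 0.114),
  and the network consumes the resulting single channel (224×224×1 after
  standardisation).
* **Augmentation** (training only): rotation ±15°, horizontal flip,
  translation ≤10%, brightness/contrast ±10%, each applied independently
  with probability 0.5 — the bounds are stated, the per-transform
  probability is not.
* **Split rounding.** The 7:3 split allocates `round_half_up(0.7·n)` per
  class; this is the only rounding rule that reproduces every cell of the
  published per-class split table (e.g. 1645·0.7 = 1151.5 → 1152). The 15%
  internal-validation carve-out from the training portion uses the same
  rule. The 30% partition is treated as the test set (the protocol uses
  "validation" and "test" interchangeably for it).
* **Two macro-F1 conventions** (mean of per-class F1; harmonic mean of
  macro-precision and macro-recall) disagree in the fourth decimal on some
  published rows and the convention used is not recoverable, so the report
  carries both (`macro_f1`, `macro_f1_pr`).

## The phantom generator

Real MRI corpora cannot ship with the package, so `generate_phantom()`
renders a four-class stand-in that preserves the *geometric* contrasts the
architecture targets:

* an elliptical "brain" (axes ≈ 0.76 and 0.90 of the side, jittered) on a
  dark background, with low-frequency cosine texture (base 0.35, ceiling
  0.55);
* class `elongated` — a curved quadratic-Bezier strip, near-axis
  orientation (±5°), length ≈ half the image side, jagged half-width ≈ 2%
  of the side: strongly anisotropic (bounding-box aspect ≥ 3:1), the
  geometry strip pooling is built for;
* class `compact` — a disc of radius ≈ 9% of the side near the brain
  boundary;
* class `central` — a smaller disc (≈ 4.5%) near the centroid;
* class `none` — no lesion;
* lesion intensity 0.9, additive Gaussian noise σ = 0.05, everything
  clipped to [0, 1]. All parameters are jittered per seed, and the same
  seed reproduces the image bit for bit. The ground-truth lesion mask is
  retained as an attribute so tests can compare the rendered lesion against
  what the generator intended.

Class folders are named `glioma` / `meningioma` / `pituitary` / `notumor`
so the phantom loader and a real-data loader share one code path. The
phantoms emulate lesion geometry, intensity contrast, and acquisition
noise; they do **not** emulate anatomy, scanner physics, bias fields,
partial-volume effects, or inter-scanner variability. Passing tests on
phantoms therefore demonstrate that the operators, gradients, training
loop, and evaluation stack are correct and that the architecture can learn
shape-discriminative features — not that published real-data accuracies
transfer.

## Desk-scale study protocols

Training defaults (`train_config()`) follow the tuned protocol: batch 32,
learning rate 1e-4, AdamW with decoupled weight decay 1e-4, cross-entropy,
50 epochs, dropout 0.3, best-internal-validation checkpointing.

The package's own validation studies run on a single CPU core, so they use
one reduced instantiation that keeps every structural component:

* **Desk protocol** (`reduced_model_config()` + `phantom_study_run()`):
  all widths divided by four (spatial 8/16/32, residual 32/48/96/128,
  `D` = 64), 96×96 inputs, 100 phantoms per class, 7:3 split with the 15%
  internal-validation carve-out, 15 epochs, batch 32. Two deliberate
  departures from the reference hyperparameters follow from the scale:
  the learning rate is 1e-3, because this protocol takes roughly two
  orders of magnitude fewer optimiser steps than the 50-epoch full
  protocol and at 1e-4 fifteen epochs of ~7 steps barely move a freshly
  initialised network regardless of implementation; and head dropout is
  disabled, because with a few hundred training images and a handful of
  epochs dropout only slows fitting (it visibly stalls early training on
  some seeds) and adds a regularisation confound to architecture
  comparisons. The reference defaults in `train_config()` and
  `model_config()` are untouched. Under the desk protocol the full model
  reaches ≥ 90% internal-validation accuracy in at least four of five
  seeds (asserted by the acceptance tests).
* **Ablation study** (`ablation_suite()`): the same desk protocol, with
  identical data and split shared by all variants within a seed, so
  variants differ only architecturally. Running the comparison at (near)
  convergence matters: in deliberately under-trained pilots the extra head
  parameters dominate as a convergence-speed penalty and every comparison
  degenerates into noise around chance. The assertion is directional —
  with lesions whose discriminating feature is elongation, the
  strip-pooling heads should not hurt (mean test accuracy F ≥ E and
  B ≥ A over five seeds) — not a claim about absolute accuracy.

## Numerical notes

* Convolutions run through im2col + GEMM (RcppArmadillo); the backward
  pass reuses the forward's column matrix. Agreement with a quadruple-loop
  oracle is asserted to 1e-6, strip-attention recomposition to 1e-5, and
  every layer's analytic gradient against central finite differences.
* Batch statistics use the biased variance for normalisation and the
  unbiased variance for the running buffers (momentum 0.1).
* Max-pooling resolves ties to the first window element (fixed order), so
  backward passes are deterministic.
* Degenerate metric cases follow the zero convention: precision, recall,
  and F1 are 0 when their denominators vanish; per-class AUC for a class
  absent from the truth is reported as missing, not 0.
* All randomness — phantom rendering, splitting, weight initialisation,
  shuffling, augmentation, dropout — descends from explicit integer seeds
  (per-stage sub-seeds derived by a fixed mixing scheme), and training runs
  are bit-reproducible on CPU.
* OpenBLAS is pinned to one thread at package load; the many small batched
  GEMMs lose more to thread fan-out than they gain.

## Limitations

The phantom task is far easier than real MRI classification; absolute
phantom accuracies say nothing about clinical performance. Variants C and D
(residual-only) process full-resolution single-channel input without the
spatial blocks' early downsampling, making them disproportionately
expensive; they are built and smoke-tested but excluded from the default
ablation protocol. Transfer-learning initialisation is out of scope: no
pretrained weights exist for this bespoke architecture, and all training
here starts from random initialisation.
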