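---
title: "Attention feature-fusion single-shot detection: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention feature-fusion single-shot detection: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During prostate electrosurgery the surgeon must recognise the prostate
capsule — a thin, whitish, sheet-like layer of connective tissue — on an
endoscopic video feed. It is a low-contrast target on a reddish, textured
background, and mistakes risk capsule perforation. The package implements a
one-stage detector for this setting: a single-shot multibox detector (SSD)
over a VGG16 backbone, strengthened in two ways that cost little or no
computation:

1. **Residual SimAM attention.** SimAM assigns each activation $t$ in a
   channel a weight from a closed-form energy function of the channel's own
   statistics,
   $$w(t) = \sigma\!\left(\frac{(t-\mu)^2}{4(\hat\sigma^2+\lambda)} + \tfrac12\right),$$
   where $\mu$ and $\hat\sigma^2$ are the per-channel (per-image) mean and
   variance (denominator $HW-1$) and $\lambda > 0$ is a small regulariser
   (default $10^{-4}$). It has *zero* trainable parameters. A residual
   attention block computes $x + \mathrm{ReLU}(\mathrm{BN}(x \odot w(x)))$,
   optionally followed by a 2×2 stride-2 max-pool.

2. **Forward stepwise feature fusion.** Four modules push fine spatial
   detail from shallow layers up to the detection scales. At input 300:

   | module | inputs | merge | output |
   |---|---|---|---|
   | 1 | conv2_2 (150×150×128), conv3_3 (75×75×256) | concat (384) → 1×1 → 512 | 75×75×512 |
   | 2 | pooled module-1 output, conv4_3 (38×38×512) | element-wise add | 38×38×512 |
   | 3 | pooled module-2 output, fc7 (19×19×1024) | concat (1536) → 1×1 → 1024 | 19×19×1024 |
   | 4 | pooled module-3 output, conv6_2 (10×10×256) | concat (1280) → 1×1 → 256 | 10×10×256 |

   Each module ends with BatchNorm + ReLU. Module 2 merges by addition
   because both operands are 38×38×512 and the stated output is the same
   shape with no channel-reducing transform; concatenation would force an
   extra 1024→512 projection that the design never mentions.

The detection head is standard SSD: default boxes over six source scales
(the three fusion outputs plus conv7_2/conv8_2/conv9_2), scale schedule
$s_k = 0.2 + 0.7(k-1)/5$, aspect ratios $\{1, 1', 2, \frac12\}$ (plus
$\{3, \frac13\}$ on 6-anchor layers) — 8732 boxes at input 300 —
variance-scaled centre-size offset coding (0.1, 0.1, 0.2, 0.2), bipartite +
threshold-0.5 anchor matching, softmax cross-entropy with 3:1 hard-negative
mining plus smooth-L1 localisation, and greedy per-class NMS at IoU 0.45.
Ties everywhere resolve to the lowest index, which makes matching and NMS
deterministic.

## Why the stack is built from first principles

The package targets an R environment with no deep-learning framework, so the
tensor machinery is part of the artifact: convolution is im2col + GEMM in
compiled code (double precision, batched into memory-capped GEMM chunks),
max-pooling records argmax indices for its backward pass, batch
normalisation and the graph engine are plain R. Every backward pass is
validated against central finite differences in the test suite; the
detection-side algorithms (matching, NMS, VOC AP) are validated against
exhaustive brute-force oracles. One deliberate simplification: gradients do
not flow through the SimAM weight computation — the weights are treated as
constants of the backward pass (a straight-through choice). The multiplicative
attention path itself is differentiated exactly, SimAM remains
parameter-free, and training behaves well; an exact derivative of the energy
term would add cost and complexity without changing what the package
demonstrates.

## Architecture accounting

`build_backbone()` and `build_affssd()` return a complete symbolic
description (every layer, its output shape, its parameter count) before any
weights exist, and the forward pass re-asserts those shapes at run time.
Two consequences of the printed arithmetic are worth calling out:

- **conv6_2 has 256 channels** (the reference SSD uses 512) because the
  fourth fusion module concatenates a 1024-channel carry with conv6_2 into
  1280 channels; 1024 + c = 1280 forces c = 256.
- **VGG pools use ceil-mode**: 75 → 38 ahead of conv4_3 is exactly the
  Caffe convention, and it extends the builder to any even input ≥ 32
  (conv2_2 = S/2, conv3_3 = ceil(S/4); the deepest extra blocks truncate
  gracefully when the map becomes too small to convolve).

## Ablation semantics

An `ablation_config()` holds two subsets: attention layers (of conv2_2,
conv3_3, conv4_3, conv5_3) and fusion layers (of conv2_2, conv3_3, conv4_3,
fc7, conv6_2). Attention on an endpoint consumed by an active fusion module
is applied *inside* that module (that is where the full design uses it);
otherwise it is applied in place on the trunk, as in the attention-only
model. Fusion module 1 is active when conv2_2 and conv3_3 are both enabled;
modules 2–4 when conv4_3 / fc7 / conv6_2 are. A module whose carry input is
missing (its predecessor is inactive) substitutes the nearest raw backbone
map of the required shape: raw conv4_3 for module 2, pooled conv4_3 for
module 3, pooled fc7 for module 4. This makes every row of the
ablation grids runnable. The grids themselves ship as CSV data files: 14
attention rows (the full set, every 3-subset, every 2-subset, three
singletons), 11 fusion rows, and 16 combined rows (all 15 non-empty
attention subsets over the full fusion cascade, plus the fusion-only
baseline).

## The synthetic-scene generator

Real surgical video datasets of this kind are private, so the package
generates endoscopy-like scenes it can be tested against: a reddish base colour
(0.52, 0.24, 0.22) with 3-octave value noise (amplitude 0.12) for tissue
texture, and 1–3 whitish elliptical "capsule" sheets with soft edges
(softness 0.25 of the semi-minor axis), minor/major ratio 0.5–0.9, a mean
luminance lift of 0.30 over the local background, and an occasional darker
occluding band (probability 0.15). Boxes are the ellipse bounding boxes,
always fully inside the image and at least 2% of its area. Everything is
deterministic under a seed, and images are written losslessly (PNG inside
the standard VOC `JPEGImages/` directory), so datasets reproduce
byte-for-byte. The default split is 478 training and 119 test scenes — the scale of a
small corpus annotated from a handful of surgical videos; tests use much
smaller splits.

What the generator does *not* emulate: specular highlights, motion blur,
instrument occlusion, interlacing, or the true intra-class variability of
surgical video. Passing tests on these scenes demonstrates that the
architecture, losses and training loop work end to end — not clinical
performance.

## Training and problem sizes

Training is momentum SGD (momentum 0.9, weight decay 5e-4) at a default
learning rate of 1e-4, batch size 8 by default, with anchor matches precomputed
per image. Horizontal flip / photometric augmentation are deliberately
absent so runs are deterministic. Divergence (non-finite loss) aborts with
the offending iteration.

Problem sizes are chosen once for a single-CPU workflow: the shape suite
builds and runs the genuine 300-pixel model; learning-behaviour checks use a
48-pixel backbone on 96-pixel scenes (64 train / 16 test, 300 iterations,
batch 4), which preserves the full VGG16 + attention + fusion architecture
while keeping a run in the minutes range. The acceptance script reports the
loss reduction between the first and last 50 iterations of exactly that run,
together with untrained and trained test-split mAP; nothing in the vignette
or README quotes numbers that the tests or the script do not themselves
compute.

## Known limitations

- No pretrained VGG16 weights: initialisation is He-normal from a seed, and
  a user can load user-supplied weights through a checkpoint instead.
- Speed and latency are hardware-dependent and out of scope; this
  implementation optimises for verifiability, not real-time inference.
- The continuous-AP protocol is available (`protocol = "continuous"`), but
  the default is the VOC2007 11-point interpolation, consistent with the
  Caffe-SSD lineage of the design.
- Gradients are straight-through with respect to the SimAM statistics (see
  above).
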