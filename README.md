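# affssd

Single-shot detection of low-contrast targets in endoscopic imagery, in R.

During prostate electrosurgery the surgeon must spot the prostate capsule —
a whitish, sheet-like tissue layer that is hard to distinguish from the
surrounding reddish parenchyma — on a live video feed. `affssd` implements a
detector built for exactly this kind of target: an SSD300 one-stage detector
(VGG16 backbone) augmented with

- **parameter-free SimAM residual attention** on low-level convolutional
  endpoints — each activation `t` is reweighted by
  `sigmoid((t − μ)² / (4(σ² + λ)) + ½)` computed from its own channel
  statistics, adding **zero** trainable parameters; and
- **four forward stepwise feature-fusion modules** that cascade fine spatial
  detail upward: conv2_2⊕conv3_3 → 75×75×512, merged into conv4_3 →
  38×38×512, concatenated with fc7 (1536 channels) → 19×19×1024, and
  concatenated with conv6_2 (1280 channels) → 10×10×256, each ending in
  BatchNorm + ReLU.

Because no deep-learning framework is assumed, the package carries its own
compiled conv/pool kernels (im2col + GEMM via RcppArmadillo), a small graph
engine with exact backward passes, the full SSD multibox machinery (8732
default boxes, bipartite matching, hard-negative-mined multibox loss, greedy
NMS), Pascal-VOC mAP evaluation, a seeded generator of endoscopy-like
synthetic scenes with VOC XML I/O, a momentum-SGD training loop, and an
ablation-grid runner over attention/fusion layer subsets.

## Worked example

```r
library(affssd)

m <- build_affssd(backbone_config(300))
d <- model_description(m)
d[d$layer %in% c("conv2_2_relu", "fuse1_concat", "fuse1_out", "fuse2_out",
                 "fuse3_concat", "fuse3_out", "fuse4_concat", "fuse4_out"),
  c("layer", "op", "out_h", "out_w", "out_c")]
#>         layer     op out_h out_w out_c
#>  conv2_2_relu   relu   150   150   128
#>  fuse1_concat concat    75    75   384
#>     fuse1_out   relu    75    75   512
#>     fuse2_out   relu    38    38   512
#>  fuse3_concat concat    19    19  1536
#>     fuse3_out   relu    19    19  1024
#>  fuse4_concat concat    10    10  1280
#>     fuse4_out   relu    10    10   256
count_parameters(m)        # 24719860 trainable scalars
count_simam_placements(m)  # 4 (conv2_2, conv3_3, conv4_3, conv5_3) - all free

db <- generate_default_boxes(head_config())
nrow(db$boxes)             # 8732
db$per_layer_counts        # 5776 2166 600 150 36 4
```

The rows above are the detector's printed shape arithmetic: the fusion
cascade's concatenation widths (384, 1536, 1280 channels) and outputs
(75×75×512, 38×38×512, 19×19×1024, 10×10×256) fall directly out of the
backbone endpoint shapes, and the head tiles 8732 anchor boxes over the six
source scales.

Generate data, train, evaluate:

```r
mf <- generate_dataset(tempfile(), n_train = 64, n_test = 16,
                       spec = scene_spec(image_size = 96), seed = 1)
mf$classes                         # "capsule"

model <- build_affssd(backbone_config(48), num_classes = 2)
fit <- train_detector(model, mf,
                      train_config(learning_rate = 1e-4, batch_size = 4,
                                   max_iterations = 300, seed = 1))
evaluate_detector(fit$model, mf)$map
```

A scene from the generator carries its ground truth with it:

```r
sc <- generate_scene(scene_spec(image_size = 300), seed = 7)
sc$boxes
#>   xmin ymin xmax ymax   class
#> 1   30  107  105  239 capsule
#> 2   82   78  198  170 capsule
```

A command-line front end is installed with the package
(`system.file("cli", "affssd.R", package = "affssd")`) with subcommands
`generate`, `train`, `eval`, `ablate` and `visualize`.

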