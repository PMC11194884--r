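# Residual attention fusion and the four forward stepwise fusion modules,
# plus the combined detector builder. The residual attention block computes
#   y = x + ReLU(BN(SimAM(x)))           (spatial size halved if downsampling)
# and the four fusion modules cascade low-level detail upward:
#   1: RA(conv2_2)+pool || SimAM-BN-ReLU(conv3_3) -> concat(384) -> 1x1(512)
#   2: pool(f1) + RA(conv4_3)            -> add -> BN -> ReLU  (38x38x512)
#   3: pool(f2) || fc7     -> concat(1536) -> 1x1(1024)        (19x19x1024)
#   4: pool(f3) || conv6_2 -> concat(1280) -> 1x1(256)         (10x10x256)

DOWN_STRICT <- list(k = 2L, stride = 2L, pad = 0L, ceil = FALSE,
                    strict_even = TRUE)
DOWN_CEIL <- list(k = 2L, stride = 2L, pad = 0L, ceil = TRUE)

# Appends SimAM -> BN -> ReLU -> add(identity) [-> pool]; returns list(nodes,
# out = name of the final node).
ra_nodes <- function(nodes, prefix, src, downsample, lambda = 1e-4) {
  add <- function(n) { nodes[[length(nodes) + 1]] <<- n }
  add(node_spec(paste0(prefix, "_simam"), "simam", src, list(lambda = lambda)))
  add(node_spec(paste0(prefix, "_bn"), "bn", paste0(prefix, "_simam")))
  add(node_spec(paste0(prefix, "_relu"), "relu", paste0(prefix, "_bn")))
  add(node_spec(paste0(prefix, "_add"), "add",
                c(src, paste0(prefix, "_relu"))))
  out <- paste0(prefix, "_add")
  if (downsample) {
    add(node_spec(paste0(prefix, "_down"), "pool", out, DOWN_STRICT))
    out <- paste0(prefix, "_down")
  }
  list(nodes = nodes, out = out)
}

as_batch <- function(x) {
  if (length(dim(x)) == 3L) {
    dim(x) <- c(dim(x), 1L)
    attr(x, "was3d") <- TRUE
  }
  x
}

unbatch_like <- function(y, was3d) {
  attr(y, "was3d") <- NULL
  if (was3d) dim(y) <- dim(y)[1:3]
  y
}

run_block <- function(nodes, inputs, seed = 0L, training = FALSE) {
  was3d <- isTRUE(attr(inputs[[1]], "was3d"))
  m <- new_model(nodes, NA_integer_, kind = "block")
  m <- init_model_params(m, seed)
  fwd <- model_forward(m, inputs, training = training)
  last <- names(m$nodes)[length(m$nodes)]
  list(out = unbatch_like(get(last, envir = fwd$acts), was3d), model = m)
}

#' Residual attention block
#'
#' Adds an attention-reweighted, normalised, activated copy of the feature
#' map back onto itself: `x + ReLU(BN(SimAM(x)))`, optionally followed by a
#' 2x2 stride-2 max-pool. Channels are preserved; the spatial size is halved
#' exactly when `downsample` is `TRUE` (odd sizes are a shape error).
#'
#' @param x Feature map, `(H, W, C)` or `(H, W, C, N)`.
#' @param downsample Halve the spatial size after the residual fusion.
#' @param lambda SimAM variance regulariser.
#' @param seed Seed for the block's batch-norm initialisation.
#' @param training Use batch statistics in the batch-norm layer.
#' @return Feature map of shape `(H', W', C)` with `H' = H/2` iff downsampling.
#' @export
residual_attention_block <- function(x, downsample = FALSE, lambda = 1e-4,
                                     seed = 0L, training = FALSE) {
  x <- as_batch(x)
  nodes <- list(node_spec("x", "input", cfg = list(shape = dim(x)[1:3])))
  r <- ra_nodes(nodes, "ra", "x", downsample, lambda)
  run_block(r$nodes, list(x = x), seed, training)$out
}

fusion_block_nodes <- function(index, shape_a, shape_b, lambda = 1e-4,
                               with_attention = TRUE) {
  nodes <- list(node_spec("a", "input", cfg = list(shape = shape_a)),
                node_spec("b", "input", cfg = list(shape = shape_b)))
  add <- function(n) { nodes[[length(nodes) + 1]] <<- n }
  if (index == 1L) {
    if (with_attention) {
      r <- ra_nodes(nodes, "f1_a", "a", downsample = TRUE, lambda)
      nodes <- r$nodes; pa <- r$out
    } else {
      add(node_spec("f1_a_down", "pool", "a", DOWN_STRICT)); pa <- "f1_a_down"
    }
    if (with_attention) {
      add(node_spec("f1_b_simam", "simam", "b", list(lambda = lambda)))
      add(node_spec("f1_b_bn", "bn", "f1_b_simam"))
      add(node_spec("f1_b_relu", "relu", "f1_b_bn"))
      pb <- "f1_b_relu"
    } else pb <- "b"
    add(node_spec("f1_concat", "concat", c(pa, pb)))
    add(node_spec("f1_conv", "conv", "f1_concat",
                  list(k = 1L, stride = 1L, pad = 0L, dilation = 1L,
                       out_channels = 512L)))
    add(node_spec("f1_bn", "bn", "f1_conv"))
    add(node_spec("f1_out", "relu", "f1_bn"))
  } else if (index == 2L) {
    add(node_spec("f2_down", "pool", "a", DOWN_CEIL))
    if (with_attention) {
      r <- ra_nodes(nodes, "f2_b", "b", downsample = FALSE, lambda)
      nodes <- r$nodes; pb <- r$out
    } else pb <- "b"
    add(node_spec("f2_add", "add", c("f2_down", pb)))
    add(node_spec("f2_bn", "bn", "f2_add"))
    add(node_spec("f2_out", "relu", "f2_bn"))
  } else {
    pfx <- paste0("f", index)
    outc <- if (index == 3L) 1024L else 256L
    add(node_spec(paste0(pfx, "_down"), "pool", "a", DOWN_CEIL))
    add(node_spec(paste0(pfx, "_concat"), "concat",
                  c(paste0(pfx, "_down"), "b")))
    add(node_spec(paste0(pfx, "_conv"), "conv", paste0(pfx, "_concat"),
                  list(k = 1L, stride = 1L, pad = 0L, dilation = 1L,
                       out_channels = outc)))
    add(node_spec(paste0(pfx, "_bn"), "bn", paste0(pfx, "_conv")))
    add(node_spec(paste0(pfx, "_out"), "relu", paste0(pfx, "_bn")))
  }
  nodes
}

run_fusion <- function(index, a, b, lambda, seed, training, check) {
  a <- as_batch(a); b <- as_batch(b)
  if (dim(a)[4] != dim(b)[4]) stop_shape("fusion: batch sizes differ")
  check(dim(a)[1:3], dim(b)[1:3])
  nodes <- fusion_block_nodes(index, dim(a)[1:3], dim(b)[1:3], lambda)
  run_block(nodes, list(a = a, b = b), seed, training)$out
}

#' Forward feature stepwise fusion modules
#'
#' The four fusion stages of the detector, as standalone operators on feature
#' maps (each builds its block with seeded weights and runs it; inside a full
#' detector the same blocks are part of the graph and trained). At input 300:
#' module 1 maps conv2_2 (150x150x128) and conv3_3 (75x75x256) to 75x75x512
#' through a 384-channel concatenation; module 2 merges the downsampled
#' module-1 output with conv4_3 by element-wise addition to 38x38x512;
#' module 3 concatenates with fc7 (1536 channels) and reduces to 19x19x1024;
#' module 4 concatenates with conv6_2 (1280 channels) and reduces to
#' 10x10x256.
#'
#' @param conv2_2,conv3_3,conv4_3,fc7,conv6_2 Backbone endpoint activations.
#' @param f1,f2,f3 Output of the previous fusion module.
#' @param lambda SimAM variance regulariser.
#' @param seed Seed for block weight initialisation.
#' @param training Use batch statistics in batch-norm layers.
#' @return The fused feature map.
#' @export
fusion_module_1 <- function(conv2_2, conv3_3, lambda = 1e-4, seed = 0L,
                            training = FALSE) {
  run_fusion(1L, conv2_2, conv3_3, lambda, seed, training, function(sa, sb) {
    if (sa[1] %% 2L != 0L || sa[1] %/% 2L != sb[1] || sa[2] %/% 2L != sb[2])
      stop_shape("fusion module 1: expected the first map at exactly twice the spatial size of the second (got %dx%d and %dx%d)",
                 sa[1], sa[2], sb[1], sb[2])
  })
}

#' @rdname fusion_module_1
#' @export
fusion_module_2 <- function(f1, conv4_3, lambda = 1e-4, seed = 0L,
                            training = FALSE) {
  run_fusion(2L, f1, conv4_3, lambda, seed, training, function(sa, sb) {
    if (as.integer(ceiling(sa[1] / 2)) != sb[1] ||
        as.integer(ceiling(sa[2] / 2)) != sb[2])
      stop_shape("fusion module 2: downsampled carry %dx%d does not match endpoint %dx%d",
                 as.integer(ceiling(sa[1] / 2)), as.integer(ceiling(sa[2] / 2)),
                 sb[1], sb[2])
    if (sa[3] != sb[3])
      stop_shape("fusion module 2: element-wise merge of unequal channel counts (%d vs %d)",
                 sa[3], sb[3])
  })
}

#' @rdname fusion_module_1
#' @export
fusion_module_3 <- function(f2, fc7, lambda = 1e-4, seed = 0L,
                            training = FALSE) {
  run_fusion(3L, f2, fc7, lambda, seed, training, function(sa, sb) {
    if (as.integer(ceiling(sa[1] / 2)) != sb[1])
      stop_shape("fusion module 3: downsampled carry does not match fc7 spatial size")
  })
}

#' @rdname fusion_module_1
#' @export
fusion_module_4 <- function(f3, conv6_2, lambda = 1e-4, seed = 0L,
                            training = FALSE) {
  run_fusion(4L, f3, conv6_2, lambda, seed, training, function(sa, sb) {
    if (as.integer(ceiling(sa[1] / 2)) != sb[1])
      stop_shape("fusion module 4: downsampled carry does not match conv6_2 spatial size")
  })
}

ATTENTION_UNIVERSE <- c("conv2_2", "conv3_3", "conv4_3", "conv5_3")
FUSION_UNIVERSE <- c("conv2_2", "conv3_3", "conv4_3", "fc7", "conv6_2")

#' Ablation configuration
#'
#' One row of the attention/fusion ablation grids: which backbone endpoints
#' receive residual SimAM attention, and which endpoints participate in the
#' forward stepwise fusion cascade. Both sets may be empty (baseline SSD).
#'
#' @param attention_layers Subset of `conv2_2, conv3_3, conv4_3, conv5_3`.
#' @param fusion_layers Subset of `conv2_2, conv3_3, conv4_3, fc7, conv6_2`.
#' @return An `ablation_config` list.
#' @export
ablation_config <- function(attention_layers = character(),
                            fusion_layers = character()) {
  attention_layers <- unique(as.character(attention_layers))
  fusion_layers <- unique(as.character(fusion_layers))
  bad <- setdiff(attention_layers, ATTENTION_UNIVERSE)
  if (length(bad))
    stop_config("invalid attention layer(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(fusion_layers, FUSION_UNIVERSE)
  if (length(bad))
    stop_config("invalid fusion layer(s): %s", paste(bad, collapse = ", "))
  structure(list(attention_layers = attention_layers,
                 fusion_layers = fusion_layers),
            class = "ablation_config")
}

# Insert a trunk residual-attention enhancement after an endpoint tap and
# rewire all downstream consumers onto the enhanced map.
insert_trunk_attention <- function(nodes, tap, prefix, lambda) {
  idx <- match(tap, vapply(nodes, `[[`, "", "name"))
  chain <- ra_nodes(list(), prefix, tap, downsample = FALSE, lambda)
  for (i in seq_along(nodes)) {
    if (i <= idx) next
    nodes[[i]]$inputs[nodes[[i]]$inputs == tap] <- chain$out
  }
  append(nodes, chain$nodes, after = idx)
}

#' Build the attention + feature-fusion detector
#'
#' Assembles the full detector: the VGG16-SSD backbone, residual SimAM
#' attention at the configured endpoints, the active forward stepwise fusion
#' modules, and the multibox detection head. Attention on an endpoint that is
#' consumed by an active fusion module is applied inside that module;
#' otherwise it is applied in place on the trunk. A fusion module whose
#' carry input is unavailable (its predecessor is inactive) takes the raw
#' backbone endpoint at the matching scale instead, so every ablation row is
#' runnable. Detection-head sources are the fusion outputs at scales 38/19/10
#' (falling back to conv4_3 / fc7 / conv6_2 when the module is inactive)
#' plus conv7_2, conv8_2, conv9_2.
#'
#' @param backbone_config A [backbone_config()].
#' @param ablation An [ablation_config()]; the default enables everything.
#' @param num_classes Number of classes including background (default 2:
#'   background + one foreground class).
#' @param lambda SimAM variance regulariser.
#' @return An `affssd_model` with head metadata; weights unallocated.
#' @examples
#' m <- build_affssd(backbone_config(300), ablation_config(
#'   attention_layers = c("conv2_2", "conv5_3"),
#'   fusion_layers = c("conv2_2", "conv3_3", "conv4_3", "fc7", "conv6_2")))
#' m$meta$head$source_shapes
#' @export
build_affssd <- function(backbone_config = affssd::backbone_config(),
                         ablation = ablation_config(ATTENTION_UNIVERSE,
                                                    FUSION_UNIVERSE),
                         num_classes = 2L, lambda = 1e-4) {
  if (!inherits(ablation, "ablation_config"))
    ablation <- do.call(ablation_config, ablation)
  A <- ablation$attention_layers
  F_ <- ablation$fusion_layers
  bb <- build_backbone(backbone_config)
  nodes <- unname(bb$nodes)
  eps <- bb$meta$endpoints
  tap <- function(ep) unname(eps[[ep]])
  has_ep <- function(ep) ep %in% names(eps)

  m1 <- all(c("conv2_2", "conv3_3") %in% F_) && has_ep("conv3_3")
  m2 <- "conv4_3" %in% F_ && has_ep("conv4_3")
  m3 <- "fc7" %in% F_ && has_ep("fc7")
  m4 <- "conv6_2" %in% F_ && has_ep("conv6_2")

  # attention consumed inside modules vs applied on the trunk
  in_module <- c(conv2_2 = m1, conv3_3 = m1, conv4_3 = m2, conv5_3 = FALSE)
  for (ep in A) {
    if (!in_module[[ep]] && has_ep(ep))
      nodes <- insert_trunk_attention(nodes, tap(ep),
                                      paste0(ep, "_att"), lambda)
  }
  renamed <- function(ep) {
    # trunk attention output if inserted, otherwise the raw tap
    nm <- paste0(ep, "_att_add")
    if (nm %in% vapply(nodes, `[[`, "", "name")) nm else tap(ep)
  }

  add <- function(n) { nodes[[length(nodes) + 1]] <<- n }
  f1_out <- f2_out <- f3_out <- f4_out <- NULL
  if (m1) {
    if ("conv2_2" %in% A) {
      r <- ra_nodes(nodes, "fuse1_c22", tap("conv2_2"), TRUE, lambda)
      nodes <- r$nodes; pa <- r$out
    } else {
      add(node_spec("fuse1_c22_down", "pool", tap("conv2_2"), DOWN_STRICT))
      pa <- "fuse1_c22_down"
    }
    if ("conv3_3" %in% A) {
      add(node_spec("fuse1_c33_simam", "simam", tap("conv3_3"),
                    list(lambda = lambda)))
      add(node_spec("fuse1_c33_bn", "bn", "fuse1_c33_simam"))
      add(node_spec("fuse1_c33_relu", "relu", "fuse1_c33_bn"))
      pb <- "fuse1_c33_relu"
    } else pb <- tap("conv3_3")
    add(node_spec("fuse1_concat", "concat", c(pa, pb)))
    add(node_spec("fuse1_conv", "conv", "fuse1_concat",
                  list(k = 1L, stride = 1L, pad = 0L, dilation = 1L,
                       out_channels = 512L)))
    add(node_spec("fuse1_bn", "bn", "fuse1_conv"))
    add(node_spec("fuse1_out", "relu", "fuse1_bn"))
    f1_out <- "fuse1_out"
  }
  if (m2) {
    if (!is.null(f1_out)) {
      add(node_spec("fuse2_down", "pool", f1_out, DOWN_CEIL))
      carry <- "fuse2_down"
    } else carry <- renamed("conv4_3")
    if ("conv4_3" %in% A) {
      r <- ra_nodes(nodes, "fuse2_c43", tap("conv4_3"), FALSE, lambda)
      nodes <- r$nodes; pb <- r$out
    } else pb <- renamed("conv4_3")
    add(node_spec("fuse2_add", "add", c(carry, pb)))
    add(node_spec("fuse2_bn", "bn", "fuse2_add"))
    add(node_spec("fuse2_out", "relu", "fuse2_bn"))
    f2_out <- "fuse2_out"
  }
  if (m3) {
    carry_src <- if (!is.null(f2_out)) f2_out else renamed("conv4_3")
    add(node_spec("fuse3_down", "pool", carry_src, DOWN_CEIL))
    add(node_spec("fuse3_concat", "concat", c("fuse3_down", tap("fc7"))))
    add(node_spec("fuse3_conv", "conv", "fuse3_concat",
                  list(k = 1L, stride = 1L, pad = 0L, dilation = 1L,
                       out_channels = 1024L)))
    add(node_spec("fuse3_bn", "bn", "fuse3_conv"))
    add(node_spec("fuse3_out", "relu", "fuse3_bn"))
    f3_out <- "fuse3_out"
  }
  if (m4) {
    carry_src <- if (!is.null(f3_out)) f3_out else tap("fc7")
    add(node_spec("fuse4_down", "pool", carry_src, DOWN_CEIL))
    add(node_spec("fuse4_concat", "concat", c("fuse4_down", tap("conv6_2"))))
    add(node_spec("fuse4_conv", "conv", "fuse4_concat",
                  list(k = 1L, stride = 1L, pad = 0L, dilation = 1L,
                       out_channels = 256L)))
    add(node_spec("fuse4_bn", "bn", "fuse4_conv"))
    add(node_spec("fuse4_out", "relu", "fuse4_bn"))
    f4_out <- "fuse4_out"
  }

  sources <- c(
    if (!is.null(f2_out)) f2_out else renamed("conv4_3"),
    if (!is.null(f3_out)) f3_out else if (has_ep("fc7")) tap("fc7"),
    if (!is.null(f4_out)) f4_out else if (has_ep("conv6_2")) renamed("conv6_2"),
    if (has_ep("conv7_2")) tap("conv7_2"),
    if (has_ep("conv8_2")) tap("conv8_2"),
    if (has_ep("conv9_2")) tap("conv9_2"))
  anchors <- c(4L, 6L, 6L, 6L, 4L, 4L)[seq_along(sources)]

  num_classes <- as.integer(num_classes)
  for (i in seq_along(sources)) {
    add(node_spec(sprintf("loc%d", i), "conv", sources[i],
                  list(k = 3L, stride = 1L, pad = 1L, dilation = 1L,
                       out_channels = 4L * anchors[i])))
    add(node_spec(sprintf("conf%d", i), "conv", sources[i],
                  list(k = 3L, stride = 1L, pad = 1L, dilation = 1L,
                       out_channels = num_classes * anchors[i])))
  }

  model <- new_model(nodes, bb$input_size, kind = "affssd",
                     meta = list(backbone_config = bb$meta$backbone_config,
                                 ablation = ablation,
                                 endpoints = eps))
  model$meta$head <- list(
    sources = sources, anchors = anchors, num_classes = num_classes,
    source_shapes = lapply(model$nodes[sources], `[[`, "shape"))
  model
}

#' Count SimAM attention placements in a model
#' @param model An `affssd_model`.
#' @return Integer number of SimAM nodes.
#' @export
count_simam_placements <- function(model) {
  sum(vapply(model$nodes, function(n) n$op == "simam", TRUE))
}
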