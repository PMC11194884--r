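# VGG16-based SSD300 feature extractor. Endpoint activations (post-ReLU) are
# exposed by name for the attention and fusion stages. Pooling in the VGG
# trunk uses ceil-mode (Caffe convention), which is what turns 75 -> 38 ahead
# of conv4_3 at input 300 and keeps odd intermediate sizes well-defined.

ENDPOINT_CHANNELS <- c(conv2_2 = 128L, conv3_3 = 256L, conv4_3 = 512L,
                       conv5_3 = 512L, fc7 = 1024L, conv6_2 = 256L,
                       conv7_2 = 256L, conv8_2 = 256L, conv9_2 = 256L)

#' Backbone configuration
#'
#' @param input_size Square input size in pixels; must be even and at least 32.
#'   The canonical configuration is 300.
#' @param endpoint_channels Named integer vector of channel counts per
#'   endpoint. The default follows the SSD300 convention except `conv6_2`,
#'   which is 256 so that its concatenation with a 1024-channel map yields
#'   1280 channels (the shape the fourth fusion module assumes).
#' @param batchnorm_flags Named logical vector: endpoints after which a
#'   batch-norm layer is inserted into the trunk. Default: none.
#' @param pixel_means Per-channel (RGB) means subtracted during preprocessing,
#'   on the \[0, 1\] pixel scale.
#' @return A `backbone_config` list.
#' @export
backbone_config <- function(input_size = 300L,
                            endpoint_channels = ENDPOINT_CHANNELS,
                            batchnorm_flags = NULL,
                            pixel_means = c(0.485, 0.457, 0.408)) {
  input_size <- as.integer(input_size)
  if (is.na(input_size) || input_size < 32L || input_size %% 2L != 0L)
    stop_config("input_size must be an even integer >= 32 (got %s); odd sizes yield non-integer endpoint sizes",
                input_size)
  bad <- setdiff(names(endpoint_channels), names(ENDPOINT_CHANNELS))
  if (length(bad))
    stop_config("unknown endpoint name(s): %s", paste(bad, collapse = ", "))
  ch <- ENDPOINT_CHANNELS
  ch[names(endpoint_channels)] <- as.integer(endpoint_channels)
  if (!is.null(batchnorm_flags)) {
    bad <- setdiff(names(batchnorm_flags), names(ENDPOINT_CHANNELS))
    if (length(bad))
      stop_config("unknown endpoint name(s) in batchnorm_flags: %s",
                  paste(bad, collapse = ", "))
  }
  structure(list(input_size = input_size, endpoint_channels = ch,
                 batchnorm_flags = batchnorm_flags,
                 pixel_means = pixel_means),
            class = "backbone_config")
}

# Appends conv + relu (+ optional bn) nodes; returns the updated node list.
add_conv_block <- function(nodes, name, from, out_channels, k = 3L,
                           stride = 1L, pad = 1L, dilation = 1L, bn = FALSE) {
  nodes[[length(nodes) + 1]] <- node_spec(name, "conv", from,
    list(k = k, stride = stride, pad = pad, dilation = dilation,
         out_channels = as.integer(out_channels)))
  last <- name
  if (bn) {
    nodes[[length(nodes) + 1]] <- node_spec(paste0(name, "_bn"), "bn", last)
    last <- paste0(name, "_bn")
  }
  nodes[[length(nodes) + 1]] <- node_spec(paste0(name, "_relu"), "relu", last)
  nodes
}

backbone_nodes <- function(config) {
  ch <- config$endpoint_channels
  bnf <- function(ep) isTRUE(config$batchnorm_flags[[ep]])
  nodes <- list(node_spec("input", "input",
                          cfg = list(shape = c(config$input_size,
                                               config$input_size, 3L))))
  vgg <- list(
    list("conv1_1", 64L), list("conv1_2", 64L), "pool1",
    list("conv2_1", ch[["conv2_2"]]), list("conv2_2", ch[["conv2_2"]]), "pool2",
    list("conv3_1", ch[["conv3_3"]]), list("conv3_2", ch[["conv3_3"]]),
    list("conv3_3", ch[["conv3_3"]]), "pool3",
    list("conv4_1", ch[["conv4_3"]]), list("conv4_2", ch[["conv4_3"]]),
    list("conv4_3", ch[["conv4_3"]]), "pool4",
    list("conv5_1", ch[["conv5_3"]]), list("conv5_2", ch[["conv5_3"]]),
    list("conv5_3", ch[["conv5_3"]]))
  last <- "input"
  for (item in vgg) {
    if (is.character(item)) {
      nodes[[length(nodes) + 1]] <- node_spec(item, "pool", last,
        list(k = 2L, stride = 2L, pad = 0L, ceil = TRUE))
      last <- item
    } else {
      nodes <- add_conv_block(nodes, item[[1]], last, item[[2]],
                              bn = bnf(item[[1]]))
      last <- paste0(item[[1]], "_relu")
    }
  }
  # pool5 (3x3, stride 1) + dilated fc6/fc7, the standard SSD conversion of
  # VGG16's fully connected layers
  nodes[[length(nodes) + 1]] <- node_spec("pool5", "pool", last,
    list(k = 3L, stride = 1L, pad = 1L, ceil = FALSE))
  nodes <- add_conv_block(nodes, "fc6", "pool5", 1024L, k = 3L, pad = 6L,
                          dilation = 6L)
  nodes <- add_conv_block(nodes, "fc7", "fc6_relu", ch[["fc7"]], k = 1L,
                          pad = 0L, bn = bnf("fc7"))
  nodes
}

# SSD extra feature layers beyond fc7; stops early when the spatial size can
# no longer support the next convolution (small input sizes).
extra_nodes <- function(nodes, config, shapes_env = NULL) {
  ch <- config$endpoint_channels
  extras <- list(
    list("conv6", ch[["conv6_2"]], 2L, 1L),   # stride 2, pad 1
    list("conv7", ch[["conv7_2"]], 2L, 1L),
    list("conv8", ch[["conv8_2"]], 1L, 0L),   # stride 1, valid
    list("conv9", ch[["conv9_2"]], 1L, 0L))
  last <- "fc7_relu"
  # track current spatial size from a dry shape pass
  size <- current_shape(nodes, last)[1]
  for (e in extras) {
    nm <- e[[1]]; cc <- e[[2]]; st <- e[[3]]; pd <- e[[4]]
    nxt <- conv_out_len(size, 3L, st, pd)
    if (nxt < 1L || (st == 1L && size < 3L)) break
    nodes <- add_conv_block(nodes, paste0(nm, "_1"), last, max(cc %/% 2L, 32L),
                            k = 1L, pad = 0L)
    nodes <- add_conv_block(nodes, paste0(nm, "_2"), paste0(nm, "_1_relu"),
                            cc, k = 3L, stride = st, pad = pd)
    last <- paste0(nm, "_2_relu")
    size <- nxt
    if (size <= 1L && nm != "conv9") next
  }
  nodes
}

current_shape <- function(nodes, name) {
  shapes <- list()
  for (nd in nodes) {
    shapes[[nd$name]] <- infer_shape(nd$op, nd$cfg, shapes[nd$inputs], nd$name)
    if (nd$name == name) return(shapes[[nd$name]])
    last <- nd$name
  }
  shapes[[last]]
}

#' Build the VGG16-SSD backbone
#'
#' Constructs the feature extractor as a complete layer-by-layer description
#' with symbolic output shapes and endpoint taps. At input size 300 the
#' endpoint shapes are conv2_2 150x150x128, conv3_3 75x75x256, conv4_3
#' 38x38x512, conv5_3 19x19x512, fc7 19x19x1024, conv6_2 10x10x256, conv7_2
#' 5x5x256, conv8_2 3x3x256, conv9_2 1x1x256. Smaller inputs drop the deepest
#' extra blocks once their convolutions can no longer fit.
#'
#' @param config A [backbone_config()].
#' @return An `affssd_model` with `meta$endpoints` mapping endpoint names to
#'   graph nodes. Weights are not allocated; see [init_model_params()].
#' @examples
#' bb <- build_backbone(backbone_config(300))
#' subset(model_description(bb), layer == "conv2_2")
#' @export
build_backbone <- function(config = backbone_config()) {
  if (!inherits(config, "backbone_config")) config <- do.call(backbone_config, config)
  nodes <- backbone_nodes(config)
  nodes <- extra_nodes(nodes, config)
  model <- new_model(nodes, config$input_size, kind = "backbone",
                     meta = list(backbone_config = config))
  eps <- names(ENDPOINT_CHANNELS)
  tap <- paste0(eps, "_relu")
  present <- tap %in% names(model$nodes)
  model$meta$endpoints <- stats::setNames(tap[present], eps[present])
  model
}

#' Run the backbone and collect endpoint activations
#'
#' @param images A `(H, W, 3, N)` array of input images (already
#'   preprocessed / mean-subtracted as desired); `H = W = input_size`.
#' @param model A backbone or detector model with initialised weights.
#' @param training Logical; use batch statistics in any batch-norm layers.
#' @return Named list of endpoint activations, each `(h, w, c, N)`.
#' @export
forward_endpoints <- function(images, model, training = FALSE) {
  if (is.null(model$meta$endpoints))
    stop_config("model has no endpoint taps")
  fwd <- model_forward(model, images, training = training)
  lapply(as.list(model$meta$endpoints),
         function(nm) get(nm, envir = fwd$acts))
}

#' Subtract per-channel pixel means
#'
#' @param images `(H, W, 3, N)` array on the \[0, 1\] scale.
#' @param pixel_means Length-3 numeric (RGB).
#' @return Mean-subtracted array of the same shape.
#' @export
preprocess_images <- function(images, pixel_means = c(0.485, 0.457, 0.408)) {
  assert_tensor4(images, "image batch")
  for (c in 1:3) images[, , c, ] <- images[, , c, ] - pixel_means[c]
  images
}
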