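# Training loop for the detector: momentum SGD with weight decay over all
# convolution and batch-norm parameters, hard-negative-mined multibox loss,
# per-iteration curve logging, and RDS checkpoints carrying the build
# configuration so a loader can refuse mismatched architectures.

#' Training configuration
#'
#' @param learning_rate SGD learning rate (default 1e-4).
#' @param batch_size Images per iteration.
#' @param max_iterations Number of SGD iterations.
#' @param optimizer Only `"sgd_momentum"` is provided.
#' @param momentum Momentum coefficient.
#' @param weight_decay L2 penalty coefficient.
#' @param seed Seed controlling weight init and batch sampling.
#' @param eval_every Evaluate mAP on the test split every this many
#'   iterations (0 = never).
#' @param match_iou Anchor-matching IoU threshold.
#' @param neg_pos_ratio Hard-negative mining ratio.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 8L,
                         max_iterations = 100L, optimizer = "sgd_momentum",
                         momentum = 0.9, weight_decay = 5e-4, seed = 0L,
                         eval_every = 0L, match_iou = 0.5,
                         neg_pos_ratio = 3) {
  if (learning_rate < 0) stop_config("learning_rate must be >= 0")
  if (max_iterations < 1) stop_config("max_iterations must be >= 1")
  if (optimizer != "sgd_momentum")
    stop_config("unknown optimizer '%s'", optimizer)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_iterations = as.integer(max_iterations),
                 optimizer = optimizer, momentum = momentum,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 eval_every = as.integer(eval_every), match_iou = match_iou,
                 neg_pos_ratio = neg_pos_ratio),
            class = "train_config")
}

# Reshape one head layer's conv output (H, W, d*A, N) into per-image anchor
# matrices: list over images of (A*H*W) x d, anchor order matching
# generate_default_boxes (anchors fastest, then rows, then columns).
head_layer_matrices <- function(x, d) {
  dm <- dim(x)
  A <- dm[3] %/% d
  arr <- aperm(x, c(3, 1, 2, 4))             # (d*A, H, W, N)
  dim(arr) <- c(d, A * dm[1] * dm[2], dm[4])
  lapply(seq_len(dm[4]), function(n) t(arr[, , n]))
}

# Inverse of head_layer_matrices for gradients.
head_layer_from_matrices <- function(mats, hw, d) {
  N <- length(mats)
  A <- nrow(mats[[1]]) %/% (hw[1] * hw[2])
  arr <- array(0, c(d, A * hw[1] * hw[2], N))
  for (n in seq_len(N)) arr[, , n] <- t(mats[[n]])
  dim(arr) <- c(d * A, hw[1], hw[2], N)
  aperm(arr, c(2, 3, 1, 4))
}

collect_head_outputs <- function(model, fwd) {
  head <- model$meta$head
  N <- dim(get(head$sources[1], envir = fwd$acts))[4]
  nsrc <- length(head$sources)
  loc_parts <- conf_parts <- vector("list", nsrc)
  for (i in seq_len(nsrc)) {
    loc_parts[[i]] <- head_layer_matrices(
      get(sprintf("loc%d", i), envir = fwd$acts), 4L)
    conf_parts[[i]] <- head_layer_matrices(
      get(sprintf("conf%d", i), envir = fwd$acts), head$num_classes)
  }
  loc <- lapply(seq_len(N), function(n)
    do.call(rbind, lapply(loc_parts, `[[`, n)))
  conf <- lapply(seq_len(N), function(n)
    do.call(rbind, lapply(conf_parts, `[[`, n)))
  list(loc = loc, conf = conf)
}

head_gradients <- function(model, fwd, dloc_list, dconf_list) {
  head <- model$meta$head
  counts <- vapply(seq_along(head$sources), function(i) {
    s <- head$source_shapes[[i]]
    head$anchors[i] * s[1] * s[2]
  }, 0L)
  dout <- list()
  at <- 0L
  for (i in seq_along(head$sources)) {
    rows <- at + seq_len(counts[i])
    s <- head$source_shapes[[i]]
    dout[[sprintf("loc%d", i)]] <- head_layer_from_matrices(
      lapply(dloc_list, function(m) m[rows, , drop = FALSE]), s[1:2], 4L)
    dout[[sprintf("conf%d", i)]] <- head_layer_from_matrices(
      lapply(dconf_list, function(m) m[rows, , drop = FALSE]), s[1:2],
      head$num_classes)
    at <- at + counts[i]
  }
  dout
}

load_split <- function(manifest, split, input_size, pixel_means, classes) {
  ids <- manifest[[split]]
  lapply(ids, function(id) {
    ex <- load_example(manifest, id)
    S <- dim(ex$image)[1]
    img <- if (S != input_size)
      resize_bilinear(ex$image, input_size, input_size) else ex$image
    gt <- if (nrow(ex$boxes)) {
      cbind(ex$boxes$xmin, ex$boxes$ymin, ex$boxes$xmax, ex$boxes$ymax) / S
    } else matrix(numeric(0), 0, 4)
    labels <- match(ex$boxes$class, classes)
    if (anyNA(labels))
      stop_config("image %s contains class(es) not in the manifest class list",
                  id)
    list(id = id, image = preprocess_images(
      array(img, c(dim(img), 1L)), pixel_means)[, , , 1],
      gt = gt, labels = labels)
  })
}

#' Train the detector
#'
#' Runs `max_iterations` of momentum SGD on the manifest's training split.
#' Anchor matches are precomputed per image (they depend only on the ground
#' truth and the default boxes). Emits one loss entry per iteration and,
#' if `eval_every > 0`, a test-split mAP at that cadence. Aborts with the
#' offending iteration index if the loss becomes non-finite.
#'
#' @param model An `affssd_model` from [build_affssd()]; weights are
#'   initialised from `config$seed` if absent.
#' @param manifest Dataset manifest ([generate_dataset()] /
#'   [dataset_manifest()]).
#' @param config A [train_config()].
#' @param verbose Print progress every 25 iterations.
#' @return List: `model` (trained), `curve` (data frame `iteration`, `loss`,
#'   `map`), `defaults` (the default-box set used).
#' @export
train_detector <- function(model, manifest, config = train_config(),
                           verbose = FALSE) {
  has_params <- !is.null(model$nodes[["conv1_1"]]$params)
  if (!has_params) model <- init_model_params(model, config$seed)
  # private parameter copies: the optimiser updates in place
  for (i in seq_along(model$nodes))
    if (!is.null(model$nodes[[i]]$params))
      model$nodes[[i]]$params <- lapply(model$nodes[[i]]$params,
                                        function(p) p + 0)
  defaults <- generate_default_boxes(model_head_config(model))
  pixel_means <- model$meta$backbone_config$pixel_means
  classes <- manifest$classes
  data <- load_split(manifest, "train", model$input_size, pixel_means, classes)
  if (!length(data)) stop_config("empty training split")
  matches <- lapply(data, function(d)
    match_anchors(d$gt, d$labels, defaults, config$match_iou))

  state <- new.env(parent = emptyenv())
  curve <- data.frame(iteration = integer(), loss = numeric(),
                      map = numeric())
  n <- length(data)
  with_seed(config$seed + 1L, {
    for (it in seq_len(config$max_iterations)) {
      idx <- if (n <= config$batch_size) seq_len(n) else
        sample.int(n, config$batch_size)
      batch <- array(0, c(model$input_size, model$input_size, 3L,
                          length(idx)))
      for (k in seq_along(idx)) batch[, , , k] <- data[[idx[k]]]$image
      fwd <- model_forward(model, batch, training = TRUE)
      model <- apply_bn_updates(model, fwd$bn_updates)
      ho <- collect_head_outputs(model, fwd)
      total <- 0
      nm <- 0L
      dloc_list <- dconf_list <- vector("list", length(idx))
      for (k in seq_along(idx)) {
        L <- multibox_loss(ho$conf[[k]], ho$loc[[k]], matches[[idx[k]]],
                           defaults, config$neg_pos_ratio)
        total <- total + L$total
        nm <- nm + L$n_matched
        dloc_list[[k]] <- L$dloc / length(idx)
        dconf_list[[k]] <- L$dconf / length(idx)
      }
      loss <- total / length(idx)
      if (!is.finite(loss))
        stop(sprintf("training diverged (non-finite loss) at iteration %d",
                     it), call. = FALSE)
      if (config$learning_rate > 0 && nm > 0) {
        dout <- head_gradients(model, fwd, dloc_list, dconf_list)
        pgrads <- model_backward(model, fwd, dout)
        model <- sgd_momentum_step(model, pgrads, state,
                                   config$learning_rate, config$momentum,
                                   config$weight_decay)
      }
      map <- NA_real_
      if (config$eval_every > 0 && it %% config$eval_every == 0 &&
          length(manifest$test)) {
        map <- evaluate_detector(model, manifest)$map
      }
      curve <- rbind(curve, data.frame(iteration = it, loss = loss,
                                       map = map))
      if (verbose && it %% 25 == 0)
        message(sprintf("iter %d  loss %.4f", it, loss))
    }
  })
  list(model = model, curve = curve, defaults = defaults)
}

# In-place momentum update (compiled); `state` is an environment of velocity
# buffers. The training loop owns private parameter copies, so mutation is
# confined to it.
sgd_momentum_step <- function(model, pgrads, state, lr, momentum, wd) {
  for (nm in names(pgrads)) {
    params <- model$nodes[[nm]]$params
    for (field in names(pgrads[[nm]])) {
      key <- paste0(nm, ".", field)
      if (is.null(state[[key]]))
        state[[key]] <- numeric(length(params[[field]]))
      cpp_sgd_step(params[[field]], state[[key]], pgrads[[nm]][[field]],
                   lr, momentum, wd)
    }
  }
  model
}

#' Evaluate a detector on a dataset split
#'
#' Runs the model in inference mode over the split, decodes and suppresses
#' detections per image, and scores them with [voc_average_precision()].
#'
#' @param model A trained `affssd_model`.
#' @param manifest Dataset manifest.
#' @param split `"test"` or `"train"`.
#' @param conf_thresh,nms_iou,top_k Post-processing settings.
#' @param protocol AP protocol, see [voc_average_precision()].
#' @return The [voc_average_precision()] result, plus `detections`.
#' @export
evaluate_detector <- function(model, manifest, split = "test",
                              conf_thresh = 0.05, nms_iou = 0.45,
                              top_k = 200L, protocol = "voc07") {
  defaults <- generate_default_boxes(model_head_config(model))
  pixel_means <- model$meta$backbone_config$pixel_means
  classes <- manifest$classes
  if (!length(manifest[[split]])) stop_config("empty split '%s'", split)
  data <- load_split(manifest, split, model$input_size, pixel_means, classes)
  dets <- list()
  gts <- list()
  for (d in data) {
    x <- array(d$image, c(dim(d$image), 1L))
    fwd <- model_forward(model, x, training = FALSE)
    ho <- collect_head_outputs(model, fwd)
    dd <- decode_and_nms(ho$conf[[1]], ho$loc[[1]], defaults,
                         conf_thresh = conf_thresh, nms_iou = nms_iou,
                         top_k = top_k)
    if (nrow(dd)) {
      dd$image <- d$id
      dets[[length(dets) + 1]] <- dd
    }
    if (nrow(d$gt))
      gts[[length(gts) + 1]] <- data.frame(
        image = d$id, class = d$labels,
        xmin = d$gt[, 1], ymin = d$gt[, 2],
        xmax = d$gt[, 3], ymax = d$gt[, 4])
  }
  dets <- if (length(dets)) do.call(rbind, dets) else
    data.frame(image = character(), class = integer(), score = numeric(),
               xmin = numeric(), ymin = numeric(), xmax = numeric(),
               ymax = numeric())
  gts <- if (length(gts)) do.call(rbind, gts) else
    data.frame(image = character(), class = integer(), xmin = numeric(),
               ymin = numeric(), xmax = numeric(), ymax = numeric())
  res <- voc_average_precision(dets, gts, protocol = protocol)
  res$detections <- dets
  res
}

CHECKPOINT_VERSION <- "affssd-checkpoint-1"

#' Save / load a model checkpoint
#'
#' The archive embeds a version tag and the build configuration (backbone
#' config, ablation, class count); the loader rebuilds the architecture from
#' them and refuses an archive whose configuration disagrees with a model
#' passed for verification.
#'
#' @param model A model with weights.
#' @param path Destination file.
#' @return `save_checkpoint` returns the path invisibly; `load_checkpoint`
#'   returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(version = CHECKPOINT_VERSION,
               kind = model$kind,
               input_size = model$input_size,
               backbone_config = model$meta$backbone_config,
               ablation = model$meta$ablation,
               num_classes = model$meta$head$num_classes,
               params = lapply(model$nodes, `[[`, "params")),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expect Optional model whose architecture the checkpoint must match.
#' @export
load_checkpoint <- function(path, expect = NULL) {
  ck <- readRDS(path)
  if (!identical(ck$version, CHECKPOINT_VERSION))
    stop_config("unsupported checkpoint version: %s", ck$version)
  model <- if (identical(ck$kind, "affssd"))
    build_affssd(ck$backbone_config, ck$ablation, ck$num_classes)
  else build_backbone(ck$backbone_config)
  if (!is.null(expect)) {
    if (!identical(names(expect$nodes), names(model$nodes)) ||
        !identical(expect$meta$backbone_config, ck$backbone_config))
      stop_config("checkpoint configuration does not match the given model")
  }
  for (nm in names(ck$params))
    model$nodes[[nm]]$params <- ck$params[[nm]]
  model
}
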