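# A small static-graph engine for the detector. A model is an ordered list of
# named nodes (topological order); each node applies one op to the outputs of
# its input nodes. Output shapes are inferred symbolically at build time, so a
# model is a complete shape/parameter description before any weights exist.

OPS <- c("input", "conv", "relu", "bn", "pool", "simam", "add", "concat")

node_spec <- function(name, op, inputs = character(), cfg = list()) {
  stopifnot(op %in% OPS)
  list(name = name, op = op, inputs = inputs, cfg = cfg,
       shape = NULL, params = NULL)
}

conv_out_len <- function(input, k, stride, pad, dilation = 1L) {
  eff <- dilation * (k - 1L) + 1L
  (input + 2L * pad - eff) %/% stride + 1L
}

pool_out_len <- function(input, k, stride, pad, ceil_mode) {
  v <- (input + 2 * pad - k) / stride
  o <- (if (ceil_mode) ceiling(v) else floor(v)) + 1
  if (ceil_mode && (o - 1) * stride >= input + pad) o <- o - 1
  as.integer(o)
}

infer_shape <- function(op, cfg, in_shapes, name = "?") {
  if (op == "input") return(cfg$shape)
  s <- in_shapes[[1]]
  switch(op,
    conv = {
      h <- conv_out_len(s[1], cfg$k, cfg$stride, cfg$pad, cfg$dilation)
      w <- conv_out_len(s[2], cfg$k, cfg$stride, cfg$pad, cfg$dilation)
      if (h < 1 || w < 1)
        stop_shape("layer %s: convolution output would be empty", name)
      c(h, w, cfg$out_channels)
    },
    pool = {
      h <- pool_out_len(s[1], cfg$k, cfg$stride, cfg$pad, cfg$ceil)
      w <- pool_out_len(s[2], cfg$k, cfg$stride, cfg$pad, cfg$ceil)
      if (!cfg$ceil && (s[1] %% cfg$stride != 0 || s[2] %% cfg$stride != 0) &&
          isTRUE(cfg$strict_even))
        stop_shape("layer %s: odd spatial size %dx%d cannot be downsampled exactly",
                   name, s[1], s[2])
      c(h, w, s[3])
    },
    add = {
      for (o in in_shapes[-1])
        if (!all(o == s))
          stop_shape("layer %s: element-wise add of mismatched shapes [%s] vs [%s]",
                     name, paste(s, collapse = ","), paste(o, collapse = ","))
      s
    },
    concat = {
      for (o in in_shapes[-1])
        if (!all(o[1:2] == s[1:2]))
          stop_shape("layer %s: concat of mismatched spatial sizes", name)
      c(s[1], s[2], sum(vapply(in_shapes, `[`, 0L, 3L)))
    },
    s  # relu, bn, simam preserve shape
  )
}

new_model <- function(nodes, input_size, kind = "model", meta = list()) {
  names(nodes) <- vapply(nodes, `[[`, "", "name")
  if (anyDuplicated(names(nodes)))
    stop_config("duplicate layer names in model")
  shapes <- list()
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    if (nd$op != "input") {
      missing <- setdiff(nd$inputs, names(shapes))
      if (length(missing))
        stop_config("layer %s references unknown input(s): %s",
                    nd$name, paste(missing, collapse = ", "))
    }
    nodes[[i]]$shape <- infer_shape(nd$op, nd$cfg, shapes[nd$inputs], nd$name)
    if (nd$op == "conv")
      nodes[[i]]$cfg$in_channels <- shapes[[nd$inputs[1]]][3]
    shapes[[nd$name]] <- nodes[[i]]$shape
  }
  structure(list(nodes = nodes, input_size = input_size, kind = kind,
                 meta = meta),
            class = "affssd_model")
}

#' Initialise model weights
#'
#' Allocates He-normal convolution weights (zero biases) and unit-gamma /
#' zero-beta batch-norm parameters for every layer of a built model
#' description. Deterministic for a fixed seed.
#'
#' @param model An `affssd_model` (from [build_backbone()] or [build_affssd()]).
#' @param seed Integer seed for weight initialisation.
#' @return The model with `params` filled in on every parameterised node.
#' @export
init_model_params <- function(model, seed = 0L) {
  with_seed(seed, {
    shapes <- lapply(model$nodes, `[[`, "shape")
    for (i in seq_along(model$nodes)) {
      nd <- model$nodes[[i]]
      if (nd$op == "conv") {
        cin <- shapes[[nd$inputs[1]]][3]
        fan_in <- nd$cfg$k^2 * cin
        w <- array(rnorm(nd$cfg$k^2 * cin * nd$cfg$out_channels,
                         sd = sqrt(2 / fan_in)),
                   c(nd$cfg$k, nd$cfg$k, cin, nd$cfg$out_channels))
        model$nodes[[i]]$params <- list(W = w, b = numeric(nd$cfg$out_channels))
      } else if (nd$op == "bn") {
        cc <- nd$shape[3]
        model$nodes[[i]]$params <- list(
          gamma = rep(1, cc), beta = numeric(cc),
          running_mean = numeric(cc), running_var = rep(1, cc))
      }
    }
  })
  model
}

#' Count trainable parameters
#'
#' Counts the trainable scalars of a component: a whole model, a single node,
#' or a bare parameter list. Batch-norm running statistics are not trainable
#' and are excluded; SimAM attention contributes exactly zero.
#'
#' @param component An `affssd_model`, one of its nodes, or a parameter list.
#' @return Non-negative integer count.
#' @export
count_parameters <- function(component) {
  count_one <- function(nd) {
    if (is.null(nd$op)) return(0L)
    switch(nd$op,
      conv = {
        cin <- if (!is.null(nd$params)) dim(nd$params$W)[3] else nd$cfg$in_channels
        if (is.null(cin)) stop_config("cannot count an unshaped conv node")
        nd$cfg$k^2 * cin * nd$cfg$out_channels + nd$cfg$out_channels
      },
      bn = 2L * nd$shape[3],
      0L)
  }
  if (inherits(component, "affssd_model"))
    return(sum(vapply(component$nodes, count_one, 0)))
  if (!is.null(component$op)) return(count_one(component))
  if (is.list(component))  # bare parameter list (trainable fields only)
    return(sum(lengths(component[setdiff(names(component),
                                         c("running_mean", "running_var"))])))
  stop_config("cannot count parameters of this object")
}

model_forward <- function(model, x, training = FALSE) {
  input_names <- names(model$nodes)[
    vapply(model$nodes, function(n) n$op == "input", TRUE)]
  if (!is.list(x)) x <- stats::setNames(list(x), input_names[1])
  for (nm in input_names) {
    if (is.null(x[[nm]])) stop_config("missing model input '%s'", nm)
    assert_tensor4(x[[nm]], nm)
    want <- model$nodes[[nm]]$shape
    if (!all(dim(x[[nm]])[1:3] == want))
      stop_shape("input '%s' has shape [%s], model expects [%s]", nm,
                 paste(dim(x[[nm]])[1:3], collapse = ","),
                 paste(want, collapse = ","))
  }
  acts <- new.env(parent = emptyenv())
  caches <- new.env(parent = emptyenv())
  bn_updates <- list()
  for (nd in model$nodes) {
    out <- switch(nd$op,
      input = x[[nd$name]],
      conv = conv2d_forward(get(nd$inputs, envir = acts), nd$params$W,
                            nd$params$b, nd$cfg$stride, nd$cfg$pad,
                            nd$cfg$dilation),
      relu = relu_forward(get(nd$inputs, envir = acts)),
      bn = {
        r <- bn_forward(get(nd$inputs, envir = acts), nd$params$gamma,
                        nd$params$beta, nd$params$running_mean,
                        nd$params$running_var, training = training)
        assign(nd$name, r$cache, envir = caches)
        if (training)
          bn_updates[[nd$name]] <- list(running_mean = r$running_mean,
                                        running_var = r$running_var)
        r$y
      },
      pool = {
        r <- maxpool_forward(get(nd$inputs, envir = acts), nd$cfg$k,
                             nd$cfg$stride, nd$cfg$pad, nd$cfg$ceil)
        assign(nd$name, r$idx, envir = caches)
        r$y
      },
      simam = {
        w <- simam_weights(get(nd$inputs, envir = acts),
                           list(lambda = nd$cfg$lambda))
        assign(nd$name, w, envir = caches)
        get(nd$inputs, envir = acts) * w
      },
      add = Reduce(`+`, mget(nd$inputs, envir = acts)),
      concat = concat_channels(mget(nd$inputs, envir = acts)))
    expect <- nd$shape
    if (!all(dim(out)[1:3] == expect))
      stop_shape("layer %s produced [%s], expected [%s]", nd$name,
                 paste(dim(out)[1:3], collapse = ","),
                 paste(expect, collapse = ","))
    assign(nd$name, out, envir = acts)
  }
  list(acts = acts, caches = caches, bn_updates = bn_updates)
}

# Backward pass. `dout` is a named list of gradients w.r.t. the outputs of a
# subset of nodes (typically the detection-head convolutions). Returns
# per-node parameter gradients. Gradients are not propagated into the input.
# SimAM attention weights are treated as constants of the backward pass
# (straight-through on the channel statistics).
model_backward <- function(model, fwd, dout) {
  acts <- fwd$acts
  caches <- fwd$caches
  g <- new.env(parent = emptyenv())
  for (nm in names(dout)) assign(nm, dout[[nm]], envir = g)
  pgrads <- list()
  accum <- function(nm, val) {
    if (exists(nm, envir = g, inherits = FALSE))
      assign(nm, get(nm, envir = g) + val, envir = g)
    else assign(nm, val, envir = g)
  }
  for (nd in rev(model$nodes)) {
    if (nd$op == "input") next
    if (!exists(nd$name, envir = g, inherits = FALSE)) next
    dy <- get(nd$name, envir = g)
    rm(list = nd$name, envir = g)
    switch(nd$op,
      conv = {
        src <- nd$inputs
        need_dx <- !identical(model$nodes[[src]]$op, "input")
        r <- conv2d_backward(get(src, envir = acts), nd$params$W, dy,
                             nd$cfg$stride, nd$cfg$pad, nd$cfg$dilation,
                             need_dx = need_dx)
        pgrads[[nd$name]] <- list(W = r$dw, b = r$db)
        if (need_dx) accum(src, r$dx)
      },
      relu = accum(nd$inputs, relu_backward(dy, get(nd$name, envir = acts))),
      bn = {
        r <- bn_backward(dy, nd$params$gamma, get(nd$name, envir = caches))
        pgrads[[nd$name]] <- list(gamma = r$dgamma, beta = r$dbeta)
        accum(nd$inputs, r$dx)
      },
      pool = accum(nd$inputs,
                   maxpool_backward(dy, get(nd$name, envir = caches),
                                    dim(get(nd$inputs, envir = acts)))),
      simam = accum(nd$inputs, dy * get(nd$name, envir = caches)),
      add = for (src in nd$inputs) accum(src, dy),
      concat = {
        ccs <- vapply(nd$inputs, function(s) dim(get(s, envir = acts))[3], 0L)
        parts <- split_channels(dy, ccs)
        for (i in seq_along(nd$inputs)) accum(nd$inputs[i], parts[[i]])
      })
  }
  pgrads
}

apply_bn_updates <- function(model, bn_updates) {
  for (nm in names(bn_updates)) {
    model$nodes[[nm]]$params$running_mean <- bn_updates[[nm]]$running_mean
    model$nodes[[nm]]$params$running_var <- bn_updates[[nm]]$running_var
  }
  model
}

#' Tabular description of a built model
#'
#' @param model An `affssd_model`.
#' @return A data frame with one row per layer: name, op, inputs, output
#'   shape, and trainable parameter count.
#' @export
model_description <- function(model) {
  data.frame(
    layer = names(model$nodes),
    op = vapply(model$nodes, `[[`, "", "op"),
    inputs = vapply(model$nodes, function(n) paste(n$inputs, collapse = "+"), ""),
    out_h = vapply(model$nodes, function(n) n$shape[1], 0L),
    out_w = vapply(model$nodes, function(n) n$shape[2], 0L),
    out_c = vapply(model$nodes, function(n) n$shape[3], 0L),
    params = vapply(model$nodes, function(n) as.numeric(count_parameters(n)), 0),
    row.names = NULL
  )
}

#' @export
print.affssd_model <- function(x, ...) {
  cat(sprintf("<affssd_model: %s, input %dx%d, %d layers, %s parameters>\n",
              x$kind, x$input_size, x$input_size, length(x$nodes),
              format(count_parameters(x), big.mark = ",")))
  d <- model_description(x)
  d$shape <- sprintf("%dx%dx%d", d$out_h, d$out_w, d$out_c)
  print(d[, c("layer", "op", "inputs", "shape", "params")], right = FALSE)
  invisible(x)
}
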