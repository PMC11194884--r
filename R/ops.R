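# Low-level tensor ops on (H, W, C, N) arrays. Convolution and pooling call
# compiled kernels; the element-wise and normalisation ops are plain R.

conv2d_forward <- function(x, w, b = NULL, stride = 1L, pad = 0L, dilation = 1L) {
  cpp_conv2d_forward(x, dim(x), w, dim(w),
                     if (is.null(b)) numeric(0) else b,
                     as.integer(stride), as.integer(pad), as.integer(dilation))
}

conv2d_backward <- function(x, w, dy, stride = 1L, pad = 0L, dilation = 1L,
                            need_dx = TRUE) {
  cpp_conv2d_backward(x, dim(x), w, dim(w), dy, dim(dy),
                      as.integer(stride), as.integer(pad), as.integer(dilation),
                      need_dx)
}

maxpool_forward <- function(x, k = 2L, stride = 2L, pad = 0L, ceil_mode = FALSE) {
  cpp_maxpool_forward(x, dim(x), as.integer(k), as.integer(stride),
                      as.integer(pad), ceil_mode)
}

maxpool_backward <- function(dy, idx, xdim) {
  cpp_maxpool_backward(dy, idx, as.integer(xdim))
}

relu_forward <- function(x) {
  x[x < 0] <- 0
  x
}

relu_backward <- function(dy, y) {
  dy[y <= 0] <- 0
  dy
}

# Batch normalisation over (H, W, N) per channel.
# Returns activations plus the cache needed for the backward pass.
bn_forward <- function(x, gamma, beta, running_mean, running_var,
                       training = FALSE, eps = 1e-5, momentum = 0.1) {
  d <- dim(x)
  C <- d[3]
  m <- prod(d[c(1, 2, 4)])
  xp <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)   # (H*W*N) x C
  if (training) {
    mu <- colMeans(xp)
    v <- colMeans(xp^2) - mu^2
    v[v < 0] <- 0
    running_mean <- (1 - momentum) * running_mean + momentum * mu
    running_var <- (1 - momentum) * running_var + momentum * v * m / max(m - 1, 1)
  } else {
    mu <- running_mean
    v <- running_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- (xp - rep(mu, each = m)) * rep(inv_sd, each = m)
  yp <- xhat * rep(gamma, each = m) + rep(beta, each = m)
  y <- aperm(array(yp, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(y = y, cache = list(xhat = xhat, inv_sd = inv_sd, m = m, dims = d,
                           training = training),
       running_mean = running_mean, running_var = running_var)
}

bn_backward <- function(dy, gamma, cache) {
  d <- cache$dims
  C <- d[3]
  m <- cache$m
  dyp <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = C)
  dgamma <- colSums(dyp * cache$xhat)
  dbeta <- colSums(dyp)
  dxhat <- dyp * rep(gamma, each = m)
  if (cache$training) {
    # full gradient through the batch statistics
    t1 <- colSums(dxhat)
    t2 <- colSums(dxhat * cache$xhat)
    dxp <- (dxhat - rep(t1 / m, each = m) -
              cache$xhat * rep(t2 / m, each = m)) * rep(cache$inv_sd, each = m)
  } else {
    dxp <- dxhat * rep(cache$inv_sd, each = m)
  }
  dx <- aperm(array(dxp, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

concat_channels <- function(xs) {
  dims <- lapply(xs, dim)
  d1 <- dims[[1]]
  for (d in dims[-1])
    if (!all(d[c(1, 2, 4)] == d1[c(1, 2, 4)]))
      stop_shape("concat: spatial/batch dims differ: [%s] vs [%s]",
                 paste(d1, collapse = ","), paste(d, collapse = ","))
  ctot <- sum(vapply(dims, `[`, 0, 3))
  out <- array(0, c(d1[1], d1[2], ctot, d1[4]))
  at <- 0L
  for (x in xs) {
    cc <- dim(x)[3]
    out[, , at + seq_len(cc), ] <- x
    at <- at + cc
  }
  out
}

split_channels <- function(dy, channel_counts) {
  at <- 0L
  lapply(channel_counts, function(cc) {
    part <- dy[, , at + seq_len(cc), , drop = FALSE]
    at <<- at + cc
    part
  })
}
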