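#' @noRd
stop_config <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
stop_shape <- function(...) {
  e <- simpleError(sprintf(...))
  class(e) <- c("affssd_shape_error", class(e))
  stop(e)
}

#' @noRd
assert_tensor4 <- function(x, what = "input") {
  if (!is.array(x) || length(dim(x)) != 4L)
    stop_shape("%s must be a 4-d array (H, W, C, N), got dims [%s]",
               what, paste(dim(x), collapse = ", "))
  if (!all(is.finite(x)))
    stop("non-finite values in ", what, call. = FALSE)
  invisible(x)
}

#' Run an expression under a local, restored RNG state
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Bilinear resize of an (H, W, C) image array
#' @noRd
resize_bilinear <- function(img, out_h, out_w) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  ys <- if (out_h == 1) rep(1, 1) else seq(1, h, length.out = out_h)
  xs <- if (out_w == 1) rep(1, 1) else seq(1, w, length.out = out_w)
  y0 <- pmin(floor(ys), h - 1L); y1 <- y0 + 1; fy <- ys - y0
  x0 <- pmin(floor(xs), w - 1L); x1 <- x0 + 1; fx <- xs - x0
  if (h == 1) { y0 <- y1 <- rep(1, out_h); fy <- rep(0, out_h) }
  if (w == 1) { x0 <- x1 <- rep(1, out_w); fx <- rep(0, out_w) }
  out <- array(0, c(out_h, out_w, d[3]))
  for (c in seq_len(d[3])) {
    p <- img[, , c]
    a <- p[y0, x0, drop = FALSE]; b <- p[y0, x1, drop = FALSE]
    cc <- p[y1, x0, drop = FALSE]; dd <- p[y1, x1, drop = FALSE]
    top <- a * (1 - fx[col(a)]) + b * fx[col(b)]
    bot <- cc * (1 - fx[col(cc)]) + dd * fx[col(dd)]
    out[, , c] <- top * (1 - fy[row(top)]) + bot * fy[row(bot)]
  }
  out
}
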