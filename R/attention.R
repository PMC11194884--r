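#' Parameter-free SimAM attention
#'
#' SimAM derives a per-element attention weight from a closed-form energy
#' function of each activation against the statistics of its own channel:
#' for an activation `t` in a channel with mean `mu` and variance `sigma2`
#' (computed over the `H x W` plane of one image, variance with denominator
#' `H*W - 1`), the inverse energy is
#' `(t - mu)^2 / (4 * (sigma2 + lambda)) + 0.5`
#' and the weight is its logistic sigmoid. The operator has no trainable
#' parameters; `lambda` is a small positive regulariser that also keeps
#' constant channels well-defined.
#'
#' @param x A feature map: array of shape `(H, W, C)` for a single image or
#'   `(H, W, C, N)` for a batch.
#' @param params List with element `lambda` (default `1e-4`), as returned by
#'   [attention_params()].
#' @return `simam_weights()` returns the weight map (same shape as `x`, all
#'   values strictly in (0, 1)); `apply_simam()` returns `x * simam_weights(x)`.
#' @examples
#' x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
#' w <- simam_weights(x)
#' range(w)
#' y <- apply_simam(x)
#' @export
simam_weights <- function(x, params = attention_params()) {
  lambda <- params$lambda
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop_config("attention lambda must be a single positive number")
  d <- dim(x)
  single <- length(d) == 3L
  if (single) dim(x) <- c(d, 1L)
  d4 <- dim(x)
  hw <- d4[1] * d4[2]
  if (hw < 2)
    stop_config("SimAM needs at least 2 elements per channel (got %d)", hw)
  cn <- d4[3] * d4[4]
  xm <- matrix(x, nrow = hw, ncol = cn)          # per image-channel columns
  mu <- colMeans(xm)
  dsq <- (xm - rep(mu, each = hw))^2
  sigma2 <- colSums(dsq) / (hw - 1)
  einv <- dsq / rep(4 * (sigma2 + lambda), each = hw) + 0.5
  w <- 1 / (1 + exp(-einv))
  dim(w) <- d4
  if (single) dim(w) <- d
  w
}

#' @rdname simam_weights
#' @export
apply_simam <- function(x, params = attention_params()) {
  x * simam_weights(x, params)
}

#' @param lambda Positive variance regulariser (dimensionless).
#' @rdname simam_weights
#' @export
attention_params <- function(lambda = 1e-4) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop_config("attention lambda must be a single positive number")
  list(lambda = lambda)
}
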