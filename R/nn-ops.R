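# Low-level differentiable operations. Every *_fwd returns list(out, cache);
# the matching *_bwd takes (cache, dout) and returns the input gradient plus
# parameter gradients. Inputs are L x C matrices (positions x channels).

linear_fwd <- function(x, W, b) {
  out <- x %*% W
  out <- sweep(out, 2, b, "+")
  list(out = out, cache = list(x = x, W = W))
}

linear_bwd <- function(cache, dout) {
  list(dx = dout %*% t(cache$W),
       dW = t(cache$x) %*% dout,
       db = colSums(dout))
}

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(cache, dout) dout * cache

# Shift rows down by s (towards larger t), zero-filling the top.
shift_down <- function(x, s) {
  L <- nrow(x)
  if (s == 0) return(x)
  out <- matrix(0, L, ncol(x))
  if (s < L) out[(s + 1):L, ] <- x[1:(L - s), , drop = FALSE]
  out
}

shift_up <- function(x, s) {
  L <- nrow(x)
  if (s == 0) return(x)
  out <- matrix(0, L, ncol(x))
  if (s < L) out[1:(L - s), ] <- x[(s + 1):L, , drop = FALSE]
  out
}

#' Causal dilated convolution over a sequence
#'
#' Computes `o_t = sum_{i=0}^{k-1} x_{t - d*i} W_i + b`, i.e. a dilated
#' convolution whose output at position `t` depends only on positions `<= t`;
#' the implicit left padding of `(k-1)*d` zero rows keeps the output length
#' equal to the input length.
#'
#' @param x `L x C_in` matrix.
#' @param W list of `k` matrices, each `C_in x C_out` (tap `i` multiplies
#'   `x_{t - d*i}`).
#' @param b length-`C_out` bias.
#' @param dilation dilation `d >= 1`.
#' @return `L x C_out` matrix.
#' @export
causal_dilated_conv <- function(x, W, b = rep(0, ncol(W[[1]])), dilation = 1L) {
  conv_fwd(x, W, b, dilation)$out
}

conv_fwd <- function(x, W, b, dilation) {
  if (dilation < 1) stop("dilation must be >= 1", call. = FALSE)
  k <- length(W)
  out <- matrix(0, nrow(x), ncol(W[[1]]))
  for (i in seq_len(k)) {
    out <- out + shift_down(x, (i - 1L) * dilation) %*% W[[i]]
  }
  out <- sweep(out, 2, b, "+")
  list(out = out, cache = list(x = x, W = W, dilation = dilation))
}

conv_bwd <- function(cache, dout) {
  k <- length(cache$W)
  d <- cache$dilation
  dx <- matrix(0, nrow(cache$x), ncol(cache$x))
  dW <- vector("list", k)
  for (i in seq_len(k)) {
    s <- (i - 1L) * d
    dx <- dx + shift_up(dout %*% t(cache$W[[i]]), s)
    dW[[i]] <- t(shift_down(cache$x, s)) %*% dout
  }
  list(dx = dx, dW = dW, db = colSums(dout))
}

# Normalization per channel over the positions of the current sequence
# (instance-norm semantics). The statistics are a deterministic function of
# the input, so evaluation needs no stored state and train/eval behave
# identically; global frozen statistics would mismatch sequences of varying
# residue composition.
bn_fwd <- function(x, gamma, beta, eps = 1e-5) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  v <- colMeans(xc^2)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv_sd, "*")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out,
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma))
}

bn_bwd <- function(cache, dout) {
  N <- nrow(dout)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, cache$gamma, "*")
  # backprop through the per-sequence statistics
  t1 <- sweep(dxhat, 2, colSums(dxhat) / N)
  t2 <- sweep(cache$xhat, 2, colSums(dxhat * cache$xhat) / N, "*")
  dx <- sweep(t1 - t2, 2, cache$inv_sd, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Inverted dropout; draws from the current RNG stream (seeded by the caller).
dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = x, cache = NULL))
  }
  keep <- 1 - rate
  mask <- matrix(stats::runif(length(x)) < keep, nrow(x), ncol(x)) / keep
  list(out = x * mask, cache = mask)
}

dropout_bwd <- function(cache, dout) {
  if (is.null(cache)) dout else dout * cache
}

# Numerically stable row softmax.
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

softmax_bwd_rows <- function(p, dp) {
  p * (dp - rowSums(dp * p))
}
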