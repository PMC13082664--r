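#' Valid one-dimensional convolution over a multichannel window
#'
#' Computes `z[t, f] = act(sum_i <w[i, , f], x[t + i - 1, ]> + bias[f])`
#' for `t = 1 .. w - k + 1` — a "valid" (no padding) temporal convolution of
#' a single `w x C` window with `F` filters of kernel size `k`. This is the
#' reference kernel for the first stage of the 1-D CNN classifier; the
#' trainable model uses a batched equivalent that is tested against this
#' function.
#'
#' @param x numeric matrix, `w x C` (time steps by channels).
#' @param weights numeric array `k x C x F` of filter weights.
#' @param bias numeric vector of length `F`.
#' @param activation a function applied elementwise to the pre-activation,
#'   default [identity].
#' @return numeric matrix `(w - k + 1) x F`.
#' @examples
#' x <- matrix(1:3, ncol = 1)
#' w <- array(c(1, 1), dim = c(2, 1, 1))
#' conv1d_forward(x, w, 0) # [3, 5]
#' @export
conv1d_forward <- function(x, weights, bias, activation = identity) {
  x <- as.matrix(x)
  if (length(dim(weights)) != 3L) stop("`weights` must be a k x C x F array", call. = FALSE)
  k <- dim(weights)[1L]
  C <- dim(weights)[2L]
  F_ <- dim(weights)[3L]
  if (ncol(x) != C) {
    stop(sprintf("shape mismatch: window has %d channels, weights expect %d", ncol(x), C), call. = FALSE)
  }
  w <- nrow(x)
  if (k > w) stop(sprintf("kernel size %d exceeds window length %d", k, w), call. = FALSE)
  if (length(bias) != F_) stop("`bias` length must equal the number of filters", call. = FALSE)
  out <- matrix(0, w - k + 1L, F_)
  for (i in seq_len(k)) {
    wi <- matrix(weights[i, , ], C, F_)
    out <- out + x[i:(i + w - k), , drop = FALSE] %*% wi
  }
  activation(sweep(out, 2L, bias, "+"))
}

#' Sinusoidal positional encoding
#'
#' Standard fixed encoding added to per-time-step embeddings so the
#' attention layers see order information:
#' `PE[pos, 2i] = sin(pos / 10000^(2i/d))`,
#' `PE[pos, 2i+1] = cos(pos / 10000^(2i/d))`, with `pos` starting at 0.
#'
#' @param n_positions number of time steps.
#' @param d_model embedding dimension (must be even).
#' @return numeric matrix `n_positions x d_model`.
#' @export
positional_encoding <- function(n_positions, d_model) {
  if (d_model %% 2L != 0L) stop("`d_model` must be even", call. = FALSE)
  pos <- seq_len(n_positions) - 1
  i <- seq_len(d_model %/% 2L) - 1
  angle <- outer(pos, 1 / 10000^(2 * i / d_model))
  pe <- matrix(0, n_positions, d_model)
  pe[, 2 * i + 1] <- sin(angle)
  pe[, 2 * i + 2] <- cos(angle)
  pe
}

#' Scaled dot-product attention
#'
#' `softmax(Q K^T / sqrt(d_k)) V` with the softmax taken row-wise. The
#' reference (single-sequence) form of the self-attention used inside the
#' Transformer encoder blocks.
#'
#' @param Q,K,V numeric matrices; `Q` is `n_q x d_k`, `K` is `n x d_k`,
#'   `V` is `n x d_v`.
#' @param d_k key dimension used in the scaling; defaults to `ncol(K)`.
#' @return numeric matrix `n_q x d_v`.
#' @export
scaled_dot_attention <- function(Q, K, V, d_k = ncol(K)) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stop("Q and K must share the key dimension", call. = FALSE)
  if (nrow(K) != nrow(V)) stop("K and V must have the same number of rows", call. = FALSE)
  s <- Q %*% t(K) / sqrt(d_k)
  s <- s - apply(s, 1L, max)
  e <- exp(s)
  a <- e / rowSums(e)
  a %*% V
}

# Derive a reproducible child seed (kept in 32-bit integer range) from a
# base seed and a stage tag, so pipeline stages never share RNG streams.
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
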