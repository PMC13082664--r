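# The three classifier architectures. Each model is a bag of named weight
# matrices plus a config; forward passes are built on the autodiff graph so
# one code path serves training (with dropout masks and backprop) and
# inference (masks off).

#' Configuration of the 1-D CNN classifier
#'
#' Two valid-mode temporal convolution layers (shared filter count), each
#' followed by max pooling (size 2), then a dense ReLU layer with dropout
#' and a softmax output. Defaults follow the tuned values: 32 filters,
#' kernel size 1, dropout 0.3.
#'
#' @param n_filters filters per conv layer. @param kernel_size temporal
#'   kernel length. @param n_conv_layers number of conv+pool blocks.
#' @param dense_units width of the dense head. @param dropout dropout rate
#'   in `[0, 1)`. @param n_classes,w,n_channels output classes / window
#'   length / input channels. @param output_activation `"softmax"`
#'   (default; phases are mutually exclusive) or `"sigmoid"` (independent
#'   per-class activations, argmax at prediction).
#' @return a `cnn_config`.
#' @export
cnn_config <- function(n_filters = 32L, kernel_size = 1L, n_conv_layers = 2L,
                       dense_units = 64L, dropout = 0.3, n_classes = 4L,
                       w = 20L, n_channels = 12L,
                       output_activation = c("softmax", "sigmoid")) {
  cfg <- list(n_filters = as.integer(n_filters), kernel_size = as.integer(kernel_size),
              n_conv_layers = as.integer(n_conv_layers),
              dense_units = as.integer(dense_units), dropout = dropout,
              n_classes = as.integer(n_classes), w = as.integer(w),
              n_channels = as.integer(n_channels),
              output_activation = match.arg(output_activation))
  if (cfg$kernel_size < 1L) stop("kernel_size must be >= 1", call. = FALSE)
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must be in [0, 1)", call. = FALSE)
  structure(cfg, class = c("cnn_config", "model_config"))
}

#' Configuration of the hybrid LSTM+GRU classifier
#'
#' Two stacked sequence-returning LSTM layers, a GRU layer whose final
#' hidden state feeds a dense ReLU layer with dropout, then the output
#' layer. Defaults follow the tuned values: LSTM 100/100, GRU 256,
#' dense 128, dropout 0.3.
#'
#' @inheritParams cnn_config
#' @param lstm_units_1,lstm_units_2,gru_units,dense_units layer widths.
#' @return a `hybrid_config`.
#' @export
hybrid_config <- function(lstm_units_1 = 100L, lstm_units_2 = 100L,
                          gru_units = 256L, dense_units = 128L,
                          dropout = 0.3, n_classes = 4L, n_channels = 12L,
                          output_activation = c("softmax", "sigmoid")) {
  cfg <- list(lstm_units_1 = as.integer(lstm_units_1),
              lstm_units_2 = as.integer(lstm_units_2),
              gru_units = as.integer(gru_units),
              dense_units = as.integer(dense_units), dropout = dropout,
              n_classes = as.integer(n_classes), n_channels = as.integer(n_channels),
              output_activation = match.arg(output_activation))
  if (any(unlist(cfg[1:4]) < 1L)) stop("all unit counts must be >= 1", call. = FALSE)
  structure(cfg, class = c("hybrid_config", "model_config"))
}

#' Configuration of the Transformer-encoder classifier
#'
#' Per-time-step linear embedding to `d_model` plus sinusoidal positional
#' encoding, `n_layers` encoder blocks (multi-head self-attention and a
#' position-wise feed-forward network, each in a residual + layer-norm
#' arrangement), temporal pooling, and the output layer. Defaults follow
#' the tuned values: d_model 256, 1 head, 2 layers, d_ff 512, dropout 0.4.
#'
#' @inheritParams cnn_config
#' @param d_model embedding dimension (divisible by `n_heads`).
#' @param n_heads,n_layers,d_ff encoder shape.
#' @param pooling `"mean"` (default) or `"last"` temporal pooling before
#'   the head.
#' @return a `transformer_config`.
#' @export
transformer_config <- function(d_model = 256L, n_heads = 1L, n_layers = 2L,
                               d_ff = 512L, dropout = 0.4,
                               pooling = c("mean", "last"), n_classes = 4L,
                               n_channels = 12L,
                               output_activation = c("softmax", "sigmoid")) {
  cfg <- list(d_model = as.integer(d_model), n_heads = as.integer(n_heads),
              n_layers = as.integer(n_layers), d_ff = as.integer(d_ff),
              dropout = dropout, pooling = match.arg(pooling),
              n_classes = as.integer(n_classes), n_channels = as.integer(n_channels),
              output_activation = match.arg(output_activation))
  if (cfg$d_model %% cfg$n_heads != 0L) {
    stop("d_model must be divisible by n_heads", call. = FALSE)
  }
  if (cfg$d_model %% 2L != 0L) stop("d_model must be even (positional encoding)", call. = FALSE)
  structure(cfg, class = c("transformer_config", "model_config"))
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

zeros <- function(nr, nc) matrix(0, nr, nc)

init_cnn_params <- function(cfg) {
  p <- list()
  C <- cfg$n_channels
  wlen <- cfg$w
  for (l in seq_len(cfg$n_conv_layers)) {
    cin <- if (l == 1L) C else cfg$n_filters
    for (i in seq_len(cfg$kernel_size)) {
      p[[sprintf("conv%d_w%d", l, i)]] <- glorot(cin, cfg$n_filters)
    }
    p[[sprintf("conv%d_b", l)]] <- zeros(1L, cfg$n_filters)
    wlen <- (wlen - cfg$kernel_size + 1L) %/% 2L  # conv then pool(2)
    if (wlen < 1L) stop("window too short for the conv/pool stack", call. = FALSE)
  }
  p$dense_w <- glorot(wlen * cfg$n_filters, cfg$dense_units)
  p$dense_b <- zeros(1L, cfg$dense_units)
  p$out_w <- glorot(cfg$dense_units, cfg$n_classes)
  p$out_b <- zeros(1L, cfg$n_classes)
  p
}

init_rnn_gate <- function(p, name, nin, nh, ngate) {
  p[[paste0(name, "_Wx")]] <- glorot(nin, ngate * nh)
  p[[paste0(name, "_Wh")]] <- glorot(nh, ngate * nh)
  p[[paste0(name, "_b")]] <- zeros(1L, ngate * nh)
  p
}

init_hybrid_params <- function(cfg) {
  p <- list()
  p <- init_rnn_gate(p, "lstm1", cfg$n_channels, cfg$lstm_units_1, 4L)
  p <- init_rnn_gate(p, "lstm2", cfg$lstm_units_1, cfg$lstm_units_2, 4L)
  p <- init_rnn_gate(p, "gru", cfg$lstm_units_2, cfg$gru_units, 3L)
  p$dense_w <- glorot(cfg$gru_units, cfg$dense_units)
  p$dense_b <- zeros(1L, cfg$dense_units)
  p$out_w <- glorot(cfg$dense_units, cfg$n_classes)
  p$out_b <- zeros(1L, cfg$n_classes)
  p
}

init_transformer_params <- function(cfg) {
  p <- list()
  d <- cfg$d_model
  p$embed_w <- glorot(cfg$n_channels, d)
  p$embed_b <- zeros(1L, d)
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("enc%d_", l)
    p[[paste0(pre, "wq")]] <- glorot(d, d)
    p[[paste0(pre, "wk")]] <- glorot(d, d)
    p[[paste0(pre, "wv")]] <- glorot(d, d)
    p[[paste0(pre, "wo")]] <- glorot(d, d)
    p[[paste0(pre, "ln1_g")]] <- matrix(1, 1L, d)
    p[[paste0(pre, "ln1_b")]] <- zeros(1L, d)
    p[[paste0(pre, "ff_w1")]] <- glorot(d, cfg$d_ff)
    p[[paste0(pre, "ff_b1")]] <- zeros(1L, cfg$d_ff)
    p[[paste0(pre, "ff_w2")]] <- glorot(cfg$d_ff, d)
    p[[paste0(pre, "ff_b2")]] <- zeros(1L, d)
    p[[paste0(pre, "ln2_g")]] <- matrix(1, 1L, d)
    p[[paste0(pre, "ln2_b")]] <- zeros(1L, d)
  }
  p$out_w <- glorot(d, cfg$n_classes)
  p$out_b <- zeros(1L, cfg$n_classes)
  p
}

#' Build an untrained model from a configuration
#'
#' Weight initialization is Glorot-uniform, deterministic under
#' `init_seed`: two builds with the same config and seed have identical
#' parameters.
#'
#' @param cfg a `cnn_config`, `hybrid_config` or `transformer_config`.
#' @param init_seed integer seed for the initialization draw.
#' @return a `gait_model` handle.
#' @name build-models
NULL

#' @rdname build-models
#' @export
build_cnn <- function(cfg = cnn_config(), init_seed = 1L) {
  build_gait_model("cnn", cfg, init_cnn_params, init_seed)
}

#' @rdname build-models
#' @export
build_hybrid <- function(cfg = hybrid_config(), init_seed = 1L) {
  build_gait_model("hybrid", cfg, init_hybrid_params, init_seed)
}

#' @rdname build-models
#' @export
build_transformer <- function(cfg = transformer_config(), init_seed = 1L) {
  build_gait_model("transformer", cfg, init_transformer_params, init_seed)
}

build_gait_model <- function(type, cfg, init_fn, init_seed) {
  params <- with_seed(child_seed(init_seed, paste0("init_", type)), init_fn(cfg))
  structure(list(type = type, cfg = cfg, params = params,
                 init_seed = as.integer(init_seed)),
            class = "gait_model")
}

#' @export
print.gait_model <- function(x, ...) {
  cat(sprintf("<gait_model> %s, %d parameters\n", x$type, count_params(x)))
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model a `gait_model`.
#' @return integer count.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

## ---- forward passes ----------------------------------------------------

# Wrap every parameter matrix as a leaf node on graph g.
param_nodes <- function(g, params) lapply(params, function(v) ag_const(g, v))

drop_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix(stats::rbinom(nr * nc, 1L, 1 - p) / (1 - p), nr, nc)
}

# Shared tail: dense head on a b x d representation node.
head_forward <- function(g, rep_node, pn, cfg, targets, training) {
  h <- ag_relu(g, ag_add(g, ag_matmul(g, rep_node, pn$dense_w), pn$dense_b))
  if (training && cfg$dropout > 0) {
    h <- ag_dropout(g, h, drop_mask(nrow(h$value), ncol(h$value), cfg$dropout))
  }
  logits <- ag_add(g, ag_matmul(g, h, pn$out_w), pn$out_b)
  finish_output(g, logits, cfg, targets)
}

finish_output <- function(g, logits, cfg, targets) {
  if (cfg$output_activation == "sigmoid") {
    act <- 1 / (1 + exp(-logits$value))
    probs <- act / rowSums(act)
    loss <- if (is.null(targets)) NULL else ag_sigmoid_bce(g, logits, targets, cfg$n_classes)
  } else {
    z <- logits$value - apply(logits$value, 1L, max)
    ez <- exp(z)
    probs <- ez / rowSums(ez)
    loss <- if (is.null(targets)) NULL else ag_softmax_xent(g, logits, targets)
  }
  list(probs = probs, loss = loss, logits = logits)
}

# Binary cross-entropy against one-hot targets through per-class sigmoids
# (the "independent sigmoid" output reading; not the default).
ag_sigmoid_bce <- function(g, logits, target, n_classes) {
  z <- logits$value
  p <- 1 / (1 + exp(-z))
  n <- nrow(z)
  y <- matrix(0, n, n_classes)
  y[cbind(seq_len(n), target)] <- 1
  loss <- -mean(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
  ag_node(g, matrix(loss, 1L, 1L), list(logits), function(dz) {
    ag_accum(logits, as.numeric(dz) * (p - y) / (n * n_classes))
  })
}

forward_cnn <- function(g, model, xstack, b, w, targets = NULL, training = FALSE) {
  cfg <- model$cfg
  pn <- param_nodes(g, model$params)
  h <- ag_const(g, xstack)
  wlen <- w
  for (l in seq_len(cfg$n_conv_layers)) {
    wlist <- lapply(seq_len(cfg$kernel_size), function(i) pn[[sprintf("conv%d_w%d", l, i)]])
    h <- ag_relu(g, ag_conv1d(g, h, wlist, pn[[sprintf("conv%d_b", l)]], b, wlen))
    wlen <- wlen - cfg$kernel_size + 1L
    h <- ag_maxpool_time(g, h, b, wlen, 2L)
    wlen <- wlen %/% 2L
  }
  flat <- ag_flatten_time(g, h, b, wlen)
  out <- head_forward(g, flat, pn, cfg, targets, training)
  out$pnodes <- pn
  out
}

lstm_layer <- function(g, pn, name, x_steps, b, nh) {
  h <- ag_const(g, zeros(b, nh))
  cc <- ag_const(g, zeros(b, nh))
  Wx <- pn[[paste0(name, "_Wx")]]; Wh <- pn[[paste0(name, "_Wh")]]; bb <- pn[[paste0(name, "_b")]]
  out <- vector("list", length(x_steps))
  for (t in seq_along(x_steps)) {
    z <- ag_add(g, ag_add(g, ag_matmul(g, x_steps[[t]], Wx), ag_matmul(g, h, Wh)), bb)
    i <- ag_sigmoid(g, ag_colslice(g, z, 1L, nh))
    f <- ag_sigmoid(g, ag_colslice(g, z, nh + 1L, 2L * nh))
    o <- ag_sigmoid(g, ag_colslice(g, z, 2L * nh + 1L, 3L * nh))
    gt <- ag_tanh(g, ag_colslice(g, z, 3L * nh + 1L, 4L * nh))
    cc <- ag_add(g, ag_mul(g, f, cc), ag_mul(g, i, gt))
    h <- ag_mul(g, o, ag_tanh(g, cc))
    out[[t]] <- h
  }
  out
}

gru_layer_last <- function(g, pn, name, x_steps, b, nh) {
  h <- ag_const(g, zeros(b, nh))
  Wx <- pn[[paste0(name, "_Wx")]]; Wh <- pn[[paste0(name, "_Wh")]]; bb <- pn[[paste0(name, "_b")]]
  for (t in seq_along(x_steps)) {
    xW <- ag_add(g, ag_matmul(g, x_steps[[t]], Wx), bb)
    hW <- ag_matmul(g, h, Wh)
    zt <- ag_sigmoid(g, ag_add(g, ag_colslice(g, xW, 1L, nh), ag_colslice(g, hW, 1L, nh)))
    rt <- ag_sigmoid(g, ag_add(g, ag_colslice(g, xW, nh + 1L, 2L * nh),
                               ag_colslice(g, hW, nh + 1L, 2L * nh)))
    cand <- ag_tanh(g, ag_add(g, ag_colslice(g, xW, 2L * nh + 1L, 3L * nh),
                              ag_mul(g, rt, ag_colslice(g, hW, 2L * nh + 1L, 3L * nh))))
    h <- ag_add(g, ag_mul(g, ag_oneminus(g, zt), h), ag_mul(g, zt, cand))
  }
  h
}

forward_hybrid <- function(g, model, xstack, b, w, targets = NULL, training = FALSE) {
  cfg <- model$cfg
  pn <- param_nodes(g, model$params)
  x <- ag_const(g, xstack)
  steps <- lapply(seq_len(w), function(t) ag_timeslice(g, x, b, t))
  seq1 <- lstm_layer(g, pn, "lstm1", steps, b, cfg$lstm_units_1)
  seq2 <- lstm_layer(g, pn, "lstm2", seq1, b, cfg$lstm_units_2)
  last <- gru_layer_last(g, pn, "gru", seq2, b, cfg$gru_units)
  out <- head_forward(g, last, pn, cfg, targets, training)
  out$pnodes <- pn
  out
}

forward_transformer <- function(g, model, xstack, b, w, targets = NULL, training = FALSE) {
  cfg <- model$cfg
  pn <- param_nodes(g, model$params)
  d <- cfg$d_model
  x <- ag_const(g, xstack)
  h <- ag_add(g, ag_matmul(g, x, pn$embed_w), pn$embed_b)
  pe <- positional_encoding(w, d)
  pe_stacked <- pe[rep(seq_len(w), each = b), , drop = FALSE]
  h <- ag_add(g, h, ag_const(g, pe_stacked))
  dh <- d %/% cfg$n_heads
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("enc%d_", l)
    q <- ag_matmul(g, h, pn[[paste0(pre, "wq")]])
    k <- ag_matmul(g, h, pn[[paste0(pre, "wk")]])
    v <- ag_matmul(g, h, pn[[paste0(pre, "wv")]])
    heads <- lapply(seq_len(cfg$n_heads), function(hd) {
      a <- (hd - 1L) * dh + 1L
      ag_attention_seq(g,
                       ag_colslice(g, q, a, a + dh - 1L),
                       ag_colslice(g, k, a, a + dh - 1L),
                       ag_colslice(g, v, a, a + dh - 1L), b, w)
    })
    att <- Reduce(function(u, v2) ag_cbind2(g, u, v2), heads)
    att <- ag_matmul(g, att, pn[[paste0(pre, "wo")]])
    if (training && cfg$dropout > 0) {
      att <- ag_dropout(g, att, drop_mask(nrow(att$value), d, cfg$dropout))
    }
    h <- ag_layernorm(g, ag_add(g, h, att),
                      pn[[paste0(pre, "ln1_g")]], pn[[paste0(pre, "ln1_b")]])
    ff <- ag_relu(g, ag_add(g, ag_matmul(g, h, pn[[paste0(pre, "ff_w1")]]),
                            pn[[paste0(pre, "ff_b1")]]))
    ff <- ag_add(g, ag_matmul(g, ff, pn[[paste0(pre, "ff_w2")]]), pn[[paste0(pre, "ff_b2")]])
    if (training && cfg$dropout > 0) {
      ff <- ag_dropout(g, ff, drop_mask(nrow(ff$value), d, cfg$dropout))
    }
    h <- ag_layernorm(g, ag_add(g, h, ff),
                      pn[[paste0(pre, "ln2_g")]], pn[[paste0(pre, "ln2_b")]])
  }
  pooled <- if (cfg$pooling == "mean") ag_timemean(g, h, b, w) else ag_timeslice(g, h, b, w)
  logits <- ag_add(g, ag_matmul(g, pooled, pn$out_w), pn$out_b)
  out <- finish_output(g, logits, cfg, targets)
  out$pnodes <- pn
  out
}

model_forward <- function(g, model, xstack, b, w, targets = NULL, training = FALSE) {
  fn <- switch(model$type,
               cnn = forward_cnn,
               hybrid = forward_hybrid,
               transformer = forward_transformer,
               stop("unknown model type: ", model$type, call. = FALSE))
  fn(g, model, xstack, b, w, targets, training)
}

# Convert the first `idx` windows of a window_set into the stacked
# (b*w) x C layout used by the forward passes.
stack_windows <- function(inputs, idx = NULL) {
  a <- if (is.null(idx)) inputs else inputs[idx, , , drop = FALSE]
  d <- dim(a)
  dim(a) <- c(d[1L] * d[2L], d[3L])
  a
}
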