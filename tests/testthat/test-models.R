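test_that("conv1d_forward matches hand values and the nested-loop oracle", {
  # identity kernel
  x <- matrix(stats::rnorm(10), 10, 1)
  w_id <- array(1, c(1, 1, 1))
  expect_equal(conv1d_forward(x, w_id, 0), x)
  # k = 2 moving sum
  expect_equal(as.numeric(conv1d_forward(matrix(1:3, 3, 1), array(c(1, 1), c(2, 1, 1)), 0)),
               c(3, 5))
  # bias-only
  expect_equal(as.numeric(conv1d_forward(x, array(0, c(1, 1, 1)), 5)), rep(5, 10))
  # random instances vs oracle
  set.seed(1)
  for (i in 1:10) {
    k <- sample(1:4, 1); C <- sample(1:5, 1); F_ <- sample(1:4, 1)
    w_len <- k + sample(1:10, 1)
    x <- matrix(stats::rnorm(w_len * C), w_len, C)
    wt <- array(stats::rnorm(k * C * F_), c(k, C, F_))
    b <- stats::rnorm(F_)
    expect_equal(conv1d_forward(x, wt, b), oracle_conv1d(x, wt, b), tolerance = 1e-6)
  }
  expect_error(conv1d_forward(x, array(0, c(1, 3, 1)), 0), "shape mismatch")
})

test_that("positional encoding matches its closed form", {
  pe <- positional_encoding(8, 6)
  expect_equal(pe[1, ], rep(c(0, 1), 3))            # pos = 0
  expect_equal(pe[2, 1], sin(1))                     # pos = 1, i = 0
  expect_true(all(pe >= -1 & pe <= 1))
  for (pos in c(1, 5, 8)) {
    for (i in 0:2) {
      expect_equal(pe[pos, 2 * i + 1], sin((pos - 1) / 10000^(2 * i / 6)))
      expect_equal(pe[pos, 2 * i + 2], cos((pos - 1) / 10000^(2 * i / 6)))
    }
  }
  expect_error(positional_encoding(4, 5), "even")
})

test_that("scaled_dot_attention matches limits and the brute-force oracle", {
  set.seed(2)
  V <- matrix(stats::rnorm(12), 4, 3)
  K <- matrix(stats::rnorm(8), 4, 2)
  # zero queries -> uniform weights -> column means of V
  out <- scaled_dot_attention(matrix(0, 3, 2), K, V)
  expect_equal(out, matrix(rep(colMeans(V), each = 3), 3, 3), tolerance = 1e-12)
  # single time step -> output is V
  expect_equal(scaled_dot_attention(matrix(1, 1, 2), K[1, , drop = FALSE],
                                    V[1, , drop = FALSE]),
               V[1, , drop = FALSE])
  for (i in 1:10) {
    Q <- matrix(stats::rnorm(6), 3, 2)
    K2 <- matrix(stats::rnorm(6), 3, 2)
    V2 <- matrix(stats::rnorm(6), 3, 2)
    expect_equal(scaled_dot_attention(Q, K2, V2), oracle_attention(Q, K2, V2),
                 tolerance = 1e-6)
  }
  expect_error(scaled_dot_attention(matrix(0, 2, 3), K, V), "key dimension")
})

tiny_models <- function() list(
  cnn = build_cnn(cnn_config(n_filters = 3, kernel_size = 2, dense_units = 5,
                             w = 12, n_channels = 4, dropout = 0.2), init_seed = 3),
  hybrid = build_hybrid(hybrid_config(4, 3, 5, 4, dropout = 0.2, n_channels = 4),
                        init_seed = 3),
  transformer = build_transformer(transformer_config(d_model = 8, n_heads = 2,
                                                     n_layers = 2, d_ff = 10,
                                                     dropout = 0.2, n_channels = 4),
                                  init_seed = 3))

tiny_ws <- function(n = 7, w = 12, C = 4, seed = 5) {
  set.seed(seed)
  gaitphase:::new_window_set(array(stats::rnorm(n * w * C), c(n, w, C)),
                             sample(0:3, n, replace = TRUE), w, 1L,
                             data.frame(subject_id = rep("S", n),
                                        trial_id = rep("T", n),
                                        end_index = seq_len(n)))
}

test_that("built models emit probability rows and are reproducible", {
  ws <- tiny_ws()
  w12 <- function(m) if (m$type == "cnn") 12 else ws$w
  for (m in tiny_models()) {
    pred <- predict(m, ws)
    expect_equal(rowSums(pred$probs), rep(1, 7), tolerance = 1e-5)
    expect_true(all(pred$probs >= 0))
    # argmax consistency
    expect_equal(pred$labels, max.col(pred$probs, ties.method = "first") - 1L)
    # duplicate sample -> identical predictions
    ws2 <- gaitphase:::subset_window_set(ws, c(1L, 1L))
    p2 <- predict(m, ws2)$probs
    expect_equal(p2[1, ], p2[2, ])
    # deterministic rebuild
    m2 <- switch(m$type,
                 cnn = build_cnn(m$cfg, init_seed = 3),
                 hybrid = build_hybrid(m$cfg, init_seed = 3),
                 transformer = build_transformer(m$cfg, init_seed = 3))
    expect_identical(m$params, m2$params)
    expect_equal(count_params(m), count_params(m2))
    expect_equal(predict(m2, ws)$probs, pred$probs)
  }
})

test_that("permuting the batch permutes outputs identically", {
  ws <- tiny_ws(n = 9)
  perm <- c(4, 1, 9, 2, 8, 3, 7, 5, 6)
  for (m in tiny_models()) {
    p_all <- predict(m, ws)$probs
    p_perm <- predict(m, gaitphase:::subset_window_set(ws, perm))$probs
    expect_equal(p_perm, p_all[perm, ], tolerance = 1e-10)
  }
})

test_that("config invariants are enforced", {
  expect_error(cnn_config(kernel_size = 0), "kernel_size")
  expect_error(cnn_config(dropout = 1), "dropout")
  expect_error(hybrid_config(lstm_units_1 = 0), "unit counts")
  expect_error(transformer_config(d_model = 10, n_heads = 4), "divisible")
})

test_that("analytic gradients agree with finite differences", {
  ws <- tiny_ws(n = 5)
  check_param <- function(model, nm, w) {
    xs <- gaitphase:::stack_windows(ws$inputs[, 1:w, , drop = FALSE])
    tgt <- ws$targets + 1L
    g <- gaitphase:::ag_graph()
    r <- gaitphase:::model_forward(g, model, xs, 5L, w, targets = tgt)
    gaitphase:::ag_backward(g, r$loss)
    ga <- r$pnodes[[nm]]$grad
    p <- model$params[[nm]]
    idx <- seq_len(min(length(p), 12L))
    gn <- numeric(length(idx))
    for (j in seq_along(idx)) {
      for (s in c(1, -1)) {
        model$params[[nm]][idx[j]] <- p[idx[j]] + s * 1e-5
        g2 <- gaitphase:::ag_graph()
        r2 <- gaitphase:::model_forward(g2, model, xs, 5L, w, targets = tgt)
        gn[j] <- gn[j] + s * as.numeric(r2$loss$value) / 2e-5
      }
      model$params[[nm]][idx[j]] <- p[idx[j]]
    }
    expect_equal(as.numeric(ga)[idx], gn, tolerance = 1e-4)
  }
  ms <- tiny_models()
  # dropout off for gradient determinism
  for (nm in names(ms)) ms[[nm]]$cfg$dropout <- 0
  check_param(ms$cnn, "conv1_w1", 12)
  check_param(ms$cnn, "dense_w", 12)
  check_param(ms$hybrid, "lstm1_Wx", 12)
  check_param(ms$hybrid, "gru_Wh", 12)
  check_param(ms$transformer, "enc1_wq", 12)
  check_param(ms$transformer, "enc2_ff_w1", 12)
  check_param(ms$transformer, "embed_w", 12)
})
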