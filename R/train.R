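# Mini-batch training with Adam/AdamW and fixed-epoch schedules.

#' Training configuration
#'
#' Unset fields default per architecture to the tuned values: CNN — Adam,
#' batch 1024, learning rate 1e-4; hybrid LSTM+GRU — Adam, batch 1024,
#' learning rate 2.2e-3; Transformer — AdamW, batch 128, learning rate
#' 2.92e-5. The full-scale protocol trains for 80 epochs with no early
#' stopping; pass a smaller `epochs` for desk-scale runs.
#'
#' @param epochs number of passes over the training set (default 80).
#' @param batch_size minibatch size; `NULL` = per-model default.
#' @param optimizer `"adam"` or `"adamw"`; `NULL` = per-model default.
#' @param learning_rate step size; `NULL` = per-model default.
#' @param weight_decay decoupled weight decay for AdamW (default 0.01).
#' @param seed seed controlling shuffling, dropout and the validation
#'   monitoring subsample.
#' @param max_val_samples cap on the number of validation windows used for
#'   the per-epoch loss monitor (a fixed seeded subsample); `Inf` uses all.
#' @return a `train_config`.
#' @export
train_config <- function(epochs = 80L, batch_size = NULL, optimizer = NULL,
                         learning_rate = NULL, weight_decay = 0.01,
                         seed = 1L, max_val_samples = Inf) {
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (!is.null(learning_rate) && learning_rate < 0) {
    stop("learning_rate must be nonnegative", call. = FALSE)
  }
  structure(list(epochs = as.integer(epochs), batch_size = batch_size,
                 optimizer = optimizer, learning_rate = learning_rate,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 max_val_samples = max_val_samples),
            class = "train_config")
}

model_train_defaults <- function(type) {
  switch(type,
         cnn = list(batch_size = 1024L, optimizer = "adam", learning_rate = 1e-4),
         hybrid = list(batch_size = 1024L, optimizer = "adam", learning_rate = 0.0022),
         transformer = list(batch_size = 128L, optimizer = "adamw", learning_rate = 2.92e-5),
         stop("unknown model type: ", type, call. = FALSE))
}

resolve_train_config <- function(cfg, type) {
  d <- model_train_defaults(type)
  for (f in names(d)) if (is.null(cfg[[f]])) cfg[[f]] <- d[[f]]
  cfg
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_update <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, weight_decay = 0) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * gr
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * gr * gr
    step <- lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
    if (weight_decay > 0) step <- step + lr * weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = st)
}

eval_loss <- function(model, ws, idx, batch_size = 2048L) {
  total <- 0; n <- 0L
  for (chunk in split(idx, ceiling(seq_along(idx) / batch_size))) {
    b <- length(chunk)
    g <- ag_graph()
    res <- model_forward(g, model, stack_windows(ws$inputs, chunk), b, ws$w,
                         targets = ws$targets[chunk] + 1L, training = FALSE)
    total <- total + as.numeric(res$loss$value) * b
    n <- n + b
  }
  total / n
}

#' Train a model on a window set
#'
#' Fixed-epoch minibatch training (no early stopping) with cross-entropy
#' loss; per-epoch mean training loss and validation loss are recorded.
#' The whole trajectory is reproducible from `(model, data, cfg$seed)` under
#' single-threaded BLAS.
#'
#' @param model a `gait_model` from [build_cnn()], [build_hybrid()] or
#'   [build_transformer()].
#' @param train_ws training `window_set` (balance it first with
#'   [balance_classes()]; validation/test sets are never balanced).
#' @param val_ws optional validation `window_set` for loss monitoring.
#' @param cfg a [train_config()].
#' @return list with the trained `model` and `history` (data frame with
#'   `epoch`, `train_loss`, `val_loss`).
#' @export
train_model <- function(model, train_ws, val_ws = NULL, cfg = train_config()) {
  cfg <- resolve_train_config(cfg, model$type)
  n <- length(train_ws$targets)
  if (n == 0L) stop("empty training set", call. = FALSE)
  st <- adam_state(model$params)
  wd <- if (identical(cfg$optimizer, "adamw")) cfg$weight_decay else 0
  hist <- data.frame(epoch = integer(), train_loss = numeric(), val_loss = numeric())
  with_seed(child_seed(cfg$seed, paste0("train_", model$type)), {
    val_idx <- NULL
    if (!is.null(val_ws) && length(val_ws$targets) > 0L) {
      nv <- length(val_ws$targets)
      val_idx <- if (nv > cfg$max_val_samples) {
        sort(sample.int(nv, cfg$max_val_samples))
      } else seq_len(nv)
    }
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_loss <- 0
      for (bt in batches) {
        b <- length(bt)
        g <- ag_graph()
        res <- model_forward(g, model, stack_windows(train_ws$inputs, bt), b,
                             train_ws$w, targets = train_ws$targets[bt] + 1L,
                             training = TRUE)
        lv <- as.numeric(res$loss$value)
        if (!is.finite(lv)) {
          stop(sprintf("divergence: non-finite loss at epoch %d", epoch), call. = FALSE)
        }
        ep_loss <- ep_loss + lv * b
        if (cfg$learning_rate > 0) {
          ag_backward(g, res$loss)
          grads <- lapply(res$pnodes, function(nd) nd$grad)
          upd <- adam_update(model$params, grads, st, cfg$learning_rate,
                             weight_decay = wd)
          model$params <- upd$params
          st <- upd$state
        }
      }
      vl <- if (is.null(val_idx)) NA_real_ else eval_loss(model, val_ws, val_idx)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / n,
                                     val_loss = vl))
    }
  })
  list(model = model, history = hist)
}

#' Predict phase labels for a window set
#'
#' Deterministic inference (dropout disabled). The predicted label is the
#' argmax of the class probabilities.
#'
#' @param object a `gait_model`.
#' @param windows a `window_set`.
#' @param batch_size inference batch size.
#' @param ... unused.
#' @return list with `labels` (integer codes 0-3) and `probs`
#'   (`n x 4` matrix, rows summing to 1).
#' @export
predict.gait_model <- function(object, windows, batch_size = 1024L, ...) {
  n <- length(windows$targets)
  if (n == 0L) return(list(labels = integer(), probs = matrix(0, 0L, object$cfg$n_classes)))
  probs <- matrix(0, n, object$cfg$n_classes)
  for (chunk in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    g <- ag_graph()
    res <- model_forward(g, object, stack_windows(windows$inputs, chunk),
                         length(chunk), windows$w, targets = NULL, training = FALSE)
    probs[chunk, ] <- res$probs
  }
  list(labels = max.col(probs, ties.method = "first") - 1L, probs = probs)
}
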