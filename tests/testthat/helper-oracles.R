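# Independent brute-force oracles used to cross-check the package's
# numeric kernels and event logic. Deliberately naive implementations.

# Nested-loop valid 1-D convolution.
oracle_conv1d <- function(x, weights, bias) {
  k <- dim(weights)[1L]; C <- dim(weights)[2L]; F_ <- dim(weights)[3L]
  w <- nrow(x)
  out <- matrix(0, w - k + 1L, F_)
  for (t in seq_len(w - k + 1L)) {
    for (f in seq_len(F_)) {
      acc <- bias[f]
      for (i in seq_len(k)) {
        for (ch in seq_len(C)) acc <- acc + weights[i, ch, f] * x[t + i - 1L, ch]
      }
      out[t, f] <- acc
    }
  }
  out
}

# Attention with explicit exponentials, row by row.
oracle_attention <- function(Q, K, V, d_k = ncol(K)) {
  out <- matrix(0, nrow(Q), ncol(V))
  for (i in seq_len(nrow(Q))) {
    s <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d_k)
    e <- exp(s)
    a <- e / sum(e)
    for (j in seq_len(nrow(K))) out[i, ] <- out[i, ] + a[j] * V[j, ]
  }
  out
}

# Per-class TP/FP/FN metrics from raw label vectors.
oracle_macro <- function(y_true, y_pred) {
  pr <- rc <- f1 <- numeric(4)
  for (cl in 0:3) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    pr[cl + 1] <- if (tp + fp > 0) tp / (tp + fp) * 100 else NA_real_
    rc[cl + 1] <- if (tp + fn > 0) tp / (tp + fn) * 100 else NA_real_
    f1[cl + 1] <- if (!is.na(pr[cl + 1]) && !is.na(rc[cl + 1]) && pr[cl + 1] + rc[cl + 1] > 0) {
      2 * pr[cl + 1] * rc[cl + 1] / (pr[cl + 1] + rc[cl + 1])
    } else NA_real_
  }
  list(acc = mean(y_true == y_pred) * 100,
       macro_pr = mean(pr, na.rm = TRUE), macro_rc = mean(rc, na.rm = TRUE),
       macro_f1 = mean(f1, na.rm = TRUE))
}

# Debounce + edge extraction by explicit run enumeration: repeatedly delete
# the shortest run under the threshold, then read off edges.
oracle_detect <- function(contact, fs, min_gap) {
  x <- as.integer(contact)
  min_len <- min_gap * fs
  repeat {
    r <- rle(x)
    if (length(r$lengths) == 1L) break
    short <- which(r$lengths < min_len)
    if (length(short) == 0L) break
    k <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    x[starts[k]:ends[k]] <- 1L - r$values[k]
  }
  d <- diff(x)
  ev <- rbind(data.frame(type = "HS", index = which(d == 1L)),
              data.frame(type = "TO", index = which(d == -1L)))
  ev[order(ev$index), , drop = FALSE]
}

# Independent per-sample phase assignment: for sample i locate the
# enclosing [refHS, next refHS) cycle and compare i against the chain
# events directly.
oracle_phase_at <- function(i, ref_hs, ref_to, con_hs, con_to) {
  h <- max(ref_hs[ref_hs <= i], -Inf)
  if (!is.finite(h)) return(-1L)
  h2 <- suppressWarnings(min(ref_hs[ref_hs > h]))
  if (!is.finite(h2) || i >= h2) return(-1L)
  cto <- suppressWarnings(min(con_to[con_to > h]))
  chs <- suppressWarnings(min(con_hs[con_hs > cto]))
  rto <- suppressWarnings(min(ref_to[ref_to > chs]))
  if (!all(is.finite(c(cto, chs, rto)))) return(-1L)
  if (!(h < cto && cto < chs && chs < rto && rto < h2)) return(-1L)
  if (i < cto) 0L else if (i < chs) 1L else if (i < rto) 2L else 3L
}

# A short labeled synthetic trial for dataset tests.
make_test_trials <- function(n_subjects = 3L, trials_per_subject = 2L,
                             duration = 12, seed = 42L, noise = 0.3) {
  generate_dataset(gait_sim_params(n_subjects = n_subjects,
                                   trials_per_subject = trials_per_subject,
                                   trial_duration = duration,
                                   noise_sigma = noise, seed = seed))
}

# Minimal trial wrapper around arbitrary signal/labels for unit tests.
make_raw_trial <- function(imu, fs = 200, labels = NULL,
                           subject_id = "SX", trial_id = "T1") {
  n <- nrow(imu)
  colnames(imu) <- gaitphase:::imu_channel_names()
  tr <- gaitphase:::new_gait_trial(imu, integer(n), integer(n), fs = fs,
                                   subject_id = subject_id, trial_id = trial_id)
  if (!is.null(labels)) {
    tr$phases <- structure(as.integer(labels), reference_side = "right",
                           class = "phase_sequence")
  }
  tr
}
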