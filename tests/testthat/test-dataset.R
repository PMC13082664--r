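test_that("resampling preserves DC, halves the sample count, errors on bad rates", {
  n <- 48000
  imu <- matrix(rep(3.7, n * 12), n, 12)
  tr <- make_raw_trial(imu, fs = 200, labels = rep(0L, n))
  out <- resample_trial(tr, 100)
  expect_equal(nrow(out$imu), 24000L)
  expect_equal(out$fs, 100)
  expect_true(all(abs(out$imu - 3.7) < 1e-9))
  expect_error(resample_trial(tr, 150), "unsupported rate")
})

test_that("a 2 Hz sinusoid survives decimation with <1% amplitude error", {
  n <- 8000
  tt <- (seq_len(n) - 1) / 200
  imu <- matrix(sin(2 * pi * 2 * tt), n, 12)
  tr <- make_raw_trial(imu, fs = 200)
  out <- resample_trial(tr, 100)
  t2 <- (seq_len(nrow(out$imu)) - 1) / 100
  # demodulate to estimate the 2 Hz amplitude
  amp <- 2 * abs(mean(out$imu[, 1] * exp(-2i * pi * 2 * t2)))
  expect_lt(abs(amp - 1), 0.01)
})

test_that("event indices are re-indexed by the decimation factor", {
  ds <- make_test_trials(n_subjects = 1, trials_per_subject = 1, duration = 10, seed = 3)
  out <- resample_trial(ds[[1]], 100)
  expect_equal(out$events$right$index, ds[[1]]$events$right$index %/% 2L)
})

test_that("subject-wise split partitions trials with one val session per train subject", {
  ds <- make_test_trials(n_subjects = 3, trials_per_subject = 4, duration = 5, seed = 21)
  sp <- split_spec(c("S01", "S02"), "S03", seed = 5)
  parts <- split_subjects(ds, sp)
  expect_length(parts$train, 6L)
  expect_length(parts$val, 2L)
  expect_length(parts$test, 4L)
  ids <- function(x) sort(vapply(x, function(t) paste(t$subject_id, t$trial_id), character(1)))
  expect_equal(sort(c(ids(parts$train), ids(parts$val), ids(parts$test))), ids(ds))
  # determinism
  parts2 <- split_subjects(ds, sp)
  expect_identical(ids(parts$val), ids(parts2$val))
  # no subject in two partitions
  subj <- function(x) unique(vapply(x, function(t) t$subject_id, character(1)))
  expect_length(intersect(subj(parts$test), c(subj(parts$train), subj(parts$val))), 0L)
  expect_error(split_spec(c("S01"), c("S01")), "disjoint")
})

test_that("scaler standardizes the training pool and carries to val unchanged", {
  n <- 500
  set.seed(8)
  tr1 <- make_raw_trial(matrix(stats::rnorm(n * 12, mean = 2, sd = 3), n, 12))
  tr2 <- make_raw_trial(matrix(stats::rnorm(n * 12, mean = 2, sd = 3), n, 12))
  sc <- fit_scaler(list(tr1, tr2))
  pooled <- rbind(apply_scaler(sc, tr1)$imu, apply_scaler(sc, tr2)$imu)
  expect_true(all(abs(colMeans(pooled)) < 1e-6))
  expect_true(all(abs(apply(pooled, 2, function(x) sqrt(mean((x - mean(x))^2))) - 1) < 1e-6))
  # {1,3} -> {-1,1} under population sd
  tiny <- make_raw_trial(matrix(rep(c(1, 3), each = 1, times = 12), 2, 12))
  sct <- fit_scaler(list(tiny))
  expect_equal(as.numeric(apply_scaler(sct, tiny)$imu[, 1]), c(-1, 1))
  # val transformed with train stats keeps its offset
  trv <- make_raw_trial(matrix(stats::rnorm(n * 12, mean = 10), n, 12))
  expect_gt(abs(mean(apply_scaler(sc, trv)$imu)), 1)
  # degenerate channel
  degen <- make_raw_trial(cbind(matrix(stats::rnorm(n * 11), n, 11), rep(1, n)))
  expect_error(fit_scaler(list(degen)), "zero variance")
})

test_that("sliding windows implement the one-step-ahead contract", {
  n <- 100
  imu <- matrix(seq_len(n * 12), n, 12)  # recognizable values
  tr <- make_raw_trial(imu, labels = rep(c(0L, 1L, 2L, 3L), length.out = n))
  ws <- make_windows(tr, w = 20, offset = 1)
  expect_equal(length(ws$targets), 80L)
  # first sample: input rows 0..19, target = label at row 20 (0-based)
  expect_equal(ws$inputs[1, , ], imu[1:20, ])
  expect_equal(ws$targets[1], as.integer(tr$phases)[21])
  # last sample: input rows 79..98, target at row 99
  expect_equal(ws$inputs[80, , ], imu[80:99, ])
  expect_equal(ws$targets[80], as.integer(tr$phases)[100])
  expect_equal(ws$provenance$end_index[1], 19L)
  expect_equal(ws$provenance$end_index[80], 98L)

  # no room for the +1 target
  tr20 <- make_raw_trial(imu[1:20, ], labels = rep(0L, 20))
  expect_warning(ws0 <- make_windows(tr20, w = 20, offset = 1), "no windows")
  expect_length(ws0$targets, 0L)

  # UNLABELED targets are dropped
  lab <- rep(0L, n); lab[30:40] <- -1L
  trU <- make_raw_trial(imu, labels = lab)
  wsU <- make_windows(trU, w = 20, offset = 1)
  expect_equal(length(wsU$targets), 80L - 11L)
  expect_false(any(wsU$targets < 0L))
})

test_that("window count law |W| = n - w holds for random n, w", {
  set.seed(12)
  for (i in 1:20) {
    w <- sample(2:40, 1)
    n <- w + sample(1:100, 1)
    tr <- make_raw_trial(matrix(stats::rnorm(n * 12), n, 12),
                         labels = sample(0:3, n, replace = TRUE))
    ws <- make_windows(tr, w = w, offset = 1)
    expect_equal(length(ws$targets), n - w)
  }
})

test_that("balancing undersamples to the minimum class count", {
  set.seed(3)
  counts <- c(LR = 10L, LS = 30L, PSw = 12L, Sw = 28L)
  tr <- make_raw_trial(matrix(stats::rnorm(100 * 12), 100, 12),
                       labels = sample(0:3, 100, replace = TRUE))
  ws <- make_windows(tr, w = 20, offset = 1)   # 80 windows
  ws$targets <- rep(0:3, times = counts)       # exact counts for the check
  bal <- balance_classes(ws, seed = 4)
  expect_equal(as.integer(table(factor(bal$targets, levels = 0:3))), rep(10L, 4))
  expect_length(bal$targets, 40L)
  # deterministic and a subset of the input
  bal2 <- balance_classes(ws, seed = 4)
  expect_identical(bal$provenance, bal2$provenance)
  key <- function(x) paste(x$provenance$end_index, x$targets)
  expect_true(all(key(bal) %in% key(ws)))
  # already balanced input keeps its counts
  wsb <- gaitphase:::subset_window_set(ws, c(1:10, 11:20, 41:50, 69:78))
  balb <- balance_classes(wsb, seed = 1)
  expect_equal(table(balb$targets), table(wsb$targets))
  # zero-count class
  ws2 <- gaitphase:::subset_window_set(ws, which(ws$targets != 2L))
  expect_error(balance_classes(ws2), "zero samples")
})

test_that("balancing roughly preserves class-conditional input means", {
  ds <- make_test_trials(n_subjects = 2, trials_per_subject = 1, duration = 20, seed = 77)
  ws <- bind_window_sets(lapply(ds, make_windows))
  bal <- balance_classes(ws, seed = 9)
  for (cl in 0:3) {
    m_before <- mean(ws$inputs[ws$targets == cl, , ])
    m_after <- mean(bal$inputs[bal$targets == cl, , ])
    expect_lt(abs(m_before - m_after), 0.05)
  }
})
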