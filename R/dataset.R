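# From labeled trials to model-ready sample sets: resampling, subject-wise
# splitting, per-channel standardization, sliding-window construction with
# one-step-ahead targets, and training-set class balancing.

#' Low-pass filter and decimate a trial to a lower sampling rate
#'
#' IMU channels are filtered with a zero-phase (symmetric, centered)
#' Hamming-windowed-sinc FIR low-pass at `0.4 * fs_out` Hz and then
#' decimated by the integer factor `fs / fs_out`. Contact channels and
#' phase labels are decimated by plain index selection (no filtering, they
#' are categorical); event indices are re-indexed by integer division.
#'
#' @param trial a `gait_trial`.
#' @param fs_out target rate in Hz; `trial$fs` must be an integer multiple.
#' @param taps one-sided FIR length (default 32, i.e. 65 taps).
#' @return the resampled `gait_trial`.
#' @export
resample_trial <- function(trial, fs_out, taps = 32L) {
  fs_in <- trial$fs
  factor <- fs_in / fs_out
  if (abs(factor - round(factor)) > 1e-9 || factor < 1) {
    stop(sprintf("unsupported rate: %g Hz is not an integer divisor of %g Hz", fs_out, fs_in),
         call. = FALSE)
  }
  factor <- as.integer(round(factor))
  n <- nrow(trial$imu)
  keep <- seq(1L, n, by = factor)
  if (factor > 1L) {
    h <- fir_lowpass(0.4 * fs_out / fs_in, taps)
    imu <- apply(trial$imu, 2L, filt_zero_phase, h = h)
  } else {
    imu <- trial$imu
  }
  imu <- imu[keep, , drop = FALSE]
  reindex <- function(ev) {
    if (is.null(ev)) return(NULL)
    out <- new_gait_events(ev$type, ev$index %/% factor, side = attr(ev, "side"))
    validate_events(out, "resampled events")
    out
  }
  phases <- if (!is.null(trial$phases)) {
    structure(as.integer(trial$phases)[keep],
              reference_side = attr(trial$phases, "reference_side"),
              class = "phase_sequence")
  } else NULL
  new_gait_trial(imu, trial$contact_left[keep], trial$contact_right[keep],
                 fs = fs_out, subject_id = trial$subject_id, trial_id = trial$trial_id,
                 events = if (is.null(trial$events)) NULL else lapply(trial$events, reindex),
                 phases = phases, reference_side = trial$reference_side)
}

# Hamming-windowed sinc low-pass; fc is the cutoff as a fraction of the
# input sampling rate. Normalized to unit DC gain.
fir_lowpass <- function(fc, taps = 32L) {
  nn <- (-taps):taps
  h <- 2 * fc * sinc(2 * fc * nn)
  win <- 0.54 + 0.46 * cos(pi * nn / taps)
  h <- h * win
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Zero-phase filtering via symmetric FIR with reflection padding.
filt_zero_phase <- function(x, h) {
  L <- (length(h) - 1L) %/% 2L
  n <- length(x)
  pad <- c(x[(L + 1L):2L], x, x[(n - 1L):(n - L)])
  y <- stats::filter(pad, h, sides = 2L)
  as.numeric(y[(L + 1L):(L + n)])
}

#' Subject-wise train/validation/test split specification
#'
#' @param train_subjects,test_subjects disjoint character vectors of subject
#'   ids.
#' @param seed seed for the per-subject validation-session draw.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(train_subjects, test_subjects, seed = 1L) {
  if (length(intersect(train_subjects, test_subjects)) > 0L) {
    stop("train and test subject sets must be disjoint", call. = FALSE)
  }
  structure(list(train_subjects = train_subjects,
                 test_subjects = test_subjects,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Split trials subject-wise into train / validation / test
#'
#' All sessions of test subjects go to the test set. For each training
#' subject one session (seeded draw) becomes validation and the rest
#' training, so validation monitors unseen sessions of seen subjects while
#' the test set contains only unseen subjects.
#'
#' @param trials list of `gait_trial`.
#' @param spec a [split_spec()].
#' @return list with elements `train`, `val`, `test` (lists of trials).
#' @export
split_subjects <- function(trials, spec) {
  sids <- vapply(trials, function(tr) tr$subject_id, character(1))
  unknown <- setdiff(c(spec$train_subjects, spec$test_subjects), sids)
  if (length(unknown) > 0L) {
    stop("subjects not present in trials: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  test <- trials[sids %in% spec$test_subjects]
  train <- list(); val <- list()
  with_seed(child_seed(spec$seed, "split"), {
    for (s in spec$train_subjects) {
      idx <- which(sids == s)
      if (length(idx) < 2L) {
        stop(sprintf("train subject %s needs at least 2 sessions", s), call. = FALSE)
      }
      vi <- idx[sample.int(length(idx), 1L)]
      val <- c(val, trials[vi])
      train <- c(train, trials[setdiff(idx, vi)])
    }
  })
  list(train = train, val = val, test = test)
}

#' Fit a per-channel standardizer on training trials
#'
#' Computes the pooled per-channel mean and (population) standard deviation
#' over all training trials. Apply the same fitted statistics to
#' validation/test data so no information leaks from held-out trials.
#'
#' @param train_trials list of `gait_trial` (training partition only).
#' @return object of class `channel_scaler`.
#' @export
fit_scaler <- function(train_trials) {
  x <- do.call(rbind, lapply(train_trials, function(tr) tr$imu))
  m <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2L, m)^2))
  if (any(s <= 0)) {
    stop("degenerate channel(s) with zero variance: ",
         paste(colnames(x)[s <= 0], collapse = ", "), call. = FALSE)
  }
  structure(list(mean = m, sd = s), class = "channel_scaler")
}

#' Standardize a trial's IMU channels with fitted statistics
#' @param scaler a [fit_scaler()] result.
#' @param trial a `gait_trial`.
#' @return the trial with standardized `imu`.
#' @export
apply_scaler <- function(scaler, trial) {
  trial$imu <- sweep(sweep(trial$imu, 2L, scaler$mean), 2L, scaler$sd, "/")
  trial
}

new_window_set <- function(inputs, targets, w, offset, provenance) {
  structure(list(inputs = inputs, targets = as.integer(targets),
                 w = as.integer(w), offset = as.integer(offset),
                 provenance = provenance),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d samples, w = %d, offset = +%d, %d channels\n",
              length(x$targets), x$w, x$offset, dim(x$inputs)[3L]))
  tab <- table(factor(x$targets, levels = 0:3, labels = phase_names))
  print(tab)
  invisible(x)
}

#' Build sliding-window one-step-ahead samples from a labeled trial
#'
#' Window `j` (stride 1) takes input rows `j .. j+w-1` and the label at row
#' `j+w-1+offset` as its target. Windows whose target row falls beyond the
#' trial end or is UNLABELED are dropped; a fully labeled trial with
#' `offset = 1` yields exactly `n - w` samples.
#'
#' @param trial a `gait_trial` with `phases`.
#' @param w window length in time steps (default 20).
#' @param offset one-step-ahead prediction offset (default 1).
#' @return a `window_set` with `inputs` (`m x w x 12` array), integer
#'   `targets` and a provenance data frame (`subject_id`, `trial_id`,
#'   `end_index`, 0-based index of the last input row).
#' @export
make_windows <- function(trial, w = 20L, offset = 1L) {
  if (is.null(trial$phases)) stop("trial has no phase labels", call. = FALSE)
  n <- nrow(trial$imu)
  w <- as.integer(w); offset <- as.integer(offset)
  n_win <- n - w + 1L - offset
  if (n_win < 1L) {
    warning(sprintf("trial %s/%s too short for w=%d, offset=%d: no windows",
                    trial$subject_id, trial$trial_id, w, offset))
    return(new_window_set(array(0, c(0L, w, 12L)), integer(), w, offset,
                          data.frame(subject_id = character(), trial_id = character(),
                                     end_index = integer())))
  }
  starts <- seq_len(n_win)
  tgt <- as.integer(trial$phases)[starts + w - 1L + offset]
  keep <- tgt >= 0L
  starts <- starts[keep]; tgt <- tgt[keep]
  m <- length(starts)
  inputs <- array(0, c(m, w, 12L))
  for (t in seq_len(w)) inputs[, t, ] <- trial$imu[starts + t - 1L, , drop = FALSE]
  new_window_set(inputs, tgt, w, offset,
                 data.frame(subject_id = rep(trial$subject_id, m),
                            trial_id = rep(trial$trial_id, m),
                            end_index = starts + w - 2L))
}

#' Concatenate window sets from several trials
#' @param sets list of `window_set` with identical `w` and `offset`.
#' @return a single `window_set`.
#' @export
bind_window_sets <- function(sets) {
  sets <- sets[vapply(sets, function(s) length(s$targets) > 0L, logical(1))]
  if (length(sets) == 0L) stop("no non-empty window sets to bind", call. = FALSE)
  w <- sets[[1L]]$w; offset <- sets[[1L]]$offset
  stopifnot(all(vapply(sets, function(s) s$w == w && s$offset == offset, logical(1))))
  inputs <- do.call(abind3, lapply(sets, function(s) s$inputs))
  new_window_set(inputs,
                 unlist(lapply(sets, function(s) s$targets)),
                 w, offset,
                 do.call(rbind, lapply(sets, function(s) s$provenance)))
}

abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1L]])
  m <- sum(vapply(parts, function(p) dim(p)[1L], integer(1)))
  out <- array(0, c(m, d[2L], d[3L]))
  at <- 0L
  for (p in parts) {
    k <- dim(p)[1L]
    if (k > 0L) out[(at + 1L):(at + k), , ] <- p
    at <- at + k
  }
  out
}

subset_window_set <- function(ws, idx) {
  new_window_set(ws$inputs[idx, , , drop = FALSE], ws$targets[idx],
                 ws$w, ws$offset, ws$provenance[idx, , drop = FALSE])
}

#' Undersample a window set so all classes match the smallest class
#'
#' Uniform random undersampling without replacement, deterministic under
#' `seed`. Intended for the training pool only; validation and test sets
#' keep their natural class distribution.
#'
#' @param windows a `window_set`; every class must be present.
#' @param seed integer seed.
#' @return the balanced `window_set` (a subset of the input, provenance
#'   preserved, original relative order kept).
#' @export
balance_classes <- function(windows, seed = 1L) {
  counts <- tabulate(windows$targets + 1L, nbins = 4L)
  if (any(counts == 0L)) {
    stop("cannot balance: class(es) with zero samples: ",
         paste(phase_names[counts == 0L], collapse = ", "), call. = FALSE)
  }
  m <- min(counts)
  keep <- with_seed(child_seed(seed, "balance"), {
    unlist(lapply(0:3, function(cl) {
      idx <- which(windows$targets == cl)
      sort(idx[sample.int(length(idx), m)])
    }))
  })
  subset_window_set(windows, sort(keep))
}
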