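# Readers/writers for the canonical on-disk formats.
#
# Canonical trial CSV: header `time_s`, 12 IMU columns named
# {left|right}_{acc|gyro}_{x|y|z}, then `contact_left`, `contact_right`.
# A JSON sidecar (<trial>.events.json) carries ground-truth events and ids.
# Labels CSV: `sample_index` (0-based), `label_code`, `label_name`.

canonical_columns <- function() c("time_s", imu_channel_names(), "contact_left", "contact_right")

#' Write a trial to the canonical CSV (plus ground-truth sidecar)
#'
#' @param trial a `gait_trial`.
#' @param path output CSV path; the sidecar is written next to it as
#'   `<path minus .csv>.events.json` when the trial carries events.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  n <- nrow(trial$imu)
  df <- data.frame(time_s = (seq_len(n) - 1L) / trial$fs)
  df <- cbind(df, as.data.frame(trial$imu))
  df$contact_left <- trial$contact_left
  df$contact_right <- trial$contact_right
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(trial$events)) {
    side_list <- lapply(trial$events, function(ev) {
      data.frame(type = ev$type, index = ev$index)
    })
    jsonlite::write_json(
      list(subject_id = trial$subject_id, trial_id = trial$trial_id,
           fs = trial$fs, events = side_list),
      sub("\\.csv$", ".events.json", path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a canonical trial CSV
#'
#' Validates the header, monotonic time with a constant step (the sampling
#' rate is inferred from it), and binary contact channels. Unknown extra
#' columns are ignored with a warning. When the ground-truth sidecar is
#' present the events are attached.
#'
#' @param path CSV path.
#' @param subject_id,trial_id identifiers; defaults parsed from the sidecar
#'   or the file name.
#' @return a `gait_trial`.
#' @export
read_trial_csv <- function(path, subject_id = NULL, trial_id = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- canonical_columns()
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("format error: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(df), need)
  if (length(extra) > 0L) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  }
  tt <- df$time_s
  dt <- diff(tt)
  if (length(dt) < 1L) stop("format error: trial has fewer than 2 samples", call. = FALSE)
  if (any(dt <= 0)) {
    stop(sprintf("format error: time_s not strictly increasing at row %d",
                 which(dt <= 0)[1L] + 1L), call. = FALSE)
  }
  if (max(dt) - min(dt) > 1e-6) {
    stop(sprintf("format error: irregular sampling step at row %d",
                 which.max(abs(dt - stats::median(dt))) + 1L), call. = FALSE)
  }
  fs <- 1 / stats::median(dt)
  fs <- round(fs, 6)
  for (cc in c("contact_left", "contact_right")) {
    if (!all(df[[cc]] %in% c(0, 1))) {
      stop(sprintf("format error: column %s is not binary", cc), call. = FALSE)
    }
  }
  sidecar <- sub("\\.csv$", ".events.json", path)
  events <- NULL
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    events <- lapply(c(left = "left", right = "right"), function(s) {
      ev <- sc$events[[s]]
      new_gait_events(ev$type, ev$index, side = s)
    })
    if (is.null(subject_id)) subject_id <- sc$subject_id
    if (is.null(trial_id)) trial_id <- sc$trial_id
  }
  if (is.null(subject_id)) subject_id <- tools::file_path_sans_ext(basename(path))
  if (is.null(trial_id)) trial_id <- "T1"
  new_gait_trial(as.matrix(df[imu_channel_names()]),
                 df$contact_left, df$contact_right, fs = fs,
                 subject_id = subject_id, trial_id = trial_id, events = events)
}

#' Write / read a labels CSV
#'
#' @param phases a `phase_sequence`.
#' @param path CSV path.
#' @return `path` (writer) or the `phase_sequence` (reader).
#' @export
write_labels_csv <- function(phases, path) {
  codes <- as.integer(phases)
  utils::write.csv(
    data.frame(sample_index = seq_along(codes) - 1L,
               label_code = codes,
               label_name = ifelse(codes >= 0L, phase_names[codes + 1L], "UNLABELED")),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @param reference_side side tag stored on the returned sequence.
#' @export
read_labels_csv <- function(path, reference_side = "right") {
  df <- utils::read.csv(path)
  structure(as.integer(df$label_code), reference_side = reference_side,
            class = "phase_sequence")
}

#' Convert an external recording CSV to the canonical trial schema
#'
#' Adapter for real recordings whose column names differ from the
#' canonical schema. `mapping` names the source column for each canonical
#' column (12 IMU channels, the two contact channels and optionally
#' `time_s`; if no time column is mapped, `fs` must be given). Analog
#' contact signals are binarized at `threshold`.
#'
#' @param path source CSV.
#' @param mapping named character vector or list,
#'   `canonical_name = source_name`.
#' @param out output path for the canonical CSV.
#' @param fs sampling rate in Hz, required when `time_s` is not mapped.
#' @param threshold contact binarization threshold (default 0.5).
#' @return `out`, invisibly.
#' @export
convert_external_csv <- function(path, mapping, out, fs = NULL, threshold = 0.5) {
  src <- utils::read.csv(path, check.names = FALSE)
  mapping <- unlist(mapping)
  need <- c(imu_channel_names(), "contact_left", "contact_right")
  missing_map <- setdiff(need, names(mapping))
  if (length(missing_map) > 0L) {
    stop("mapping is missing canonical column(s): ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(unname(mapping), names(src))
  if (length(absent) > 0L) {
    stop("source file lacks mapped column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(src)
  tt <- if ("time_s" %in% names(mapping)) {
    src[[mapping[["time_s"]]]]
  } else {
    if (is.null(fs)) stop("either map time_s or supply fs", call. = FALSE)
    (seq_len(n) - 1L) / fs
  }
  df <- data.frame(time_s = tt)
  for (cc in imu_channel_names()) df[[cc]] <- src[[mapping[[cc]]]]
  df$contact_left <- binarize_contact(src[[mapping[["contact_left"]]]], threshold)
  df$contact_right <- binarize_contact(src[[mapping[["contact_right"]]]], threshold)
  utils::write.csv(df, out, row.names = FALSE)
  invisible(out)
}

## ---- published results fixtures ---------------------------------------

#' Published test-set confusion matrix of a model
#'
#' Row-normalized (percent) 4 x 4 confusion matrices of the three
#' classifiers on the full-scale benchmark, shipped as package fixtures so
#' the metric code can be checked against the printed results.
#'
#' @param model `"cnn"`, `"hybrid"` or `"transformer"`.
#' @return 4 x 4 numeric matrix (rows = actual, percentages).
#' @export
published_confusion <- function(model = c("cnn", "hybrid", "transformer")) {
  model <- match.arg(model)
  f <- system.file("extdata", sprintf("published_confusion_%s.csv", model),
                   package = "gaitphase", mustWork = TRUE)
  m <- as.matrix(utils::read.csv(f, row.names = 1L))
  dimnames(m) <- list(actual = phase_names, predicted = phase_names)
  m
}

#' Published headline metrics table
#'
#' ACC and macro precision / recall / F1 (in %) of the three classifiers on
#' the full-scale benchmark.
#'
#' @return data frame with columns `model`, `acc`, `pr`, `rc`, `f1`.
#' @export
published_metrics <- function() {
  f <- system.file("extdata", "published_metrics.csv", package = "gaitphase",
                   mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Check the published tables for internal consistency
#'
#' Recomputes macro recall as the mean diagonal of each published
#' row-normalized confusion matrix and compares it with the published RC
#' column (which is printed to two decimals).
#'
#' @param tol tolerance in percentage points (default 0.005, i.e.
#'   two-decimal rounding).
#' @return list with `ok` (logical) and a comparison `table`.
#' @export
verify_published_metrics <- function(tol = 0.005) {
  pm <- published_metrics()
  rows <- lapply(pm$model, function(m) {
    rc_hat <- macro_recall_from_rowpct(published_confusion(m))
    data.frame(model = m, rc_published = pm$rc[pm$model == m],
               rc_recomputed = round(rc_hat, 2),
               delta = abs(round(rc_hat, 2) - pm$rc[pm$model == m]))
  })
  tab <- do.call(rbind, rows)
  list(ok = all(tab$delta <= tol), table = tab)
}
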