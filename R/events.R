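# Gait event detection and four-phase labeling.
#
# Conventions used throughout the package:
#   * sample indices are 0-based (matching the on-disk CSV formats),
#   * intervals are half-open [start, end) so phase runs partition cycles
#     exactly with no double-labeled boundary sample,
#   * phase codes: LR = 0, LS = 1, PSw = 2, Sw = 3, UNLABELED = -1.

#' Phase label codes
#'
#' Named integer vector mapping phase names to label codes: Loading Response
#' (LR), Late Stance (LS, the merged Mid + Terminal Stance single-support
#' phase), Pre-Swing (PSw) and Swing (Sw).
#' @export
phase_codes <- c(LR = 0L, LS = 1L, PSw = 2L, Sw = 3L)

phase_names <- names(phase_codes)

#' Threshold an analog contact signal into a binary series
#'
#' @param contact numeric vector, finite.
#' @param threshold contact is "on" where `contact >= threshold`.
#' @return integer vector of 0/1.
#' @export
binarize_contact <- function(contact, threshold) {
  if (!all(is.finite(contact))) {
    stop("contact signal contains non-finite values", call. = FALSE)
  }
  as.integer(contact >= threshold)
}

new_gait_events <- function(type = character(), index = integer(), side = NA_character_) {
  df <- data.frame(type = type, index = as.integer(index), stringsAsFactors = FALSE)
  attr(df, "side") <- side
  class(df) <- c("gait_events", "data.frame")
  df
}

validate_events <- function(events, what = "events") {
  if (nrow(events) == 0L) return(invisible(events))
  if (any(events$index < 0L)) stop(sprintf("%s: negative sample index", what), call. = FALSE)
  if (any(diff(events$index) <= 0L)) {
    stop(sprintf("%s: indices must be strictly increasing", what), call. = FALSE)
  }
  tp <- events$type
  if (!all(tp %in% c("HS", "TO"))) stop(sprintf("%s: types must be HS or TO", what), call. = FALSE)
  if (nrow(events) > 1L && any(tp[-1L] == tp[-nrow(events)])) {
    bad <- which(tp[-1L] == tp[-nrow(events)])[1L] + 1L
    stop(sprintf("%s: HS/TO must alternate (violation at event %d, index %d)",
                 what, bad, events$index[bad]), call. = FALSE)
  }
  invisible(events)
}

#' Detect heel-strike and toe-off events from a binary contact series
#'
#' Heel strike (HS) is the index of the first 1 of each contact run
#' (0 to 1 transition); toe off (TO) the index of the first 0 after a run
#' (1 to 0 transition). A leading stance yields no HS and a trailing stance
#' no TO. Contact and no-contact segments shorter than `min_gap` seconds are
#' treated as sensor bounce and merged into their neighbors (shortest first)
#' before edges are extracted.
#'
#' @param contact integer/numeric vector of 0s and 1s.
#' @param fs sampling rate in Hz.
#' @param min_gap debounce duration in seconds (default 0.05); segments
#'   shorter than `min_gap * fs` samples are merged. Use 0 to disable.
#' @param side optional side tag ("left"/"right") attached to the result.
#' @return a `gait_events` data frame with columns `type` ("HS"/"TO") and
#'   `index` (0-based), in increasing index order.
#' @export
detect_events <- function(contact, fs, min_gap = 0.05, side = NA_character_) {
  if (length(contact) == 0L) return(new_gait_events(side = side))
  if (!all(contact %in% c(0, 1))) stop("contact series must be binary 0/1", call. = FALSE)
  x <- as.integer(contact)
  min_len <- min_gap * fs
  if (min_len > 0) {
    repeat {
      r <- rle(x)
      short <- which(r$lengths < min_len)
      if (length(short) == 0L || length(r$lengths) == 1L) break
      k <- short[which.min(r$lengths[short])]
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      x[starts[k]:ends[k]] <- 1L - r$values[k]
    }
  }
  d <- diff(x)
  hs <- which(d == 1L)       # 0-based index of first 1 = R position + 1 - 1
  to <- which(d == -1L)      # 0-based index of first 0
  ev <- rbind(
    data.frame(type = rep("HS", length(hs)), index = hs),
    data.frame(type = rep("TO", length(to)), index = to)
  )
  ev <- ev[order(ev$index), , drop = FALSE]
  out <- new_gait_events(ev$type, ev$index, side = side)
  validate_events(out, "detected events")
  out
}

next_after <- function(indices, x) {
  i <- indices[indices > x]
  if (length(i) == 0L) NA_integer_ else i[1L]
}

#' Assign four gait-phase labels from bilateral event lists
#'
#' For reference side R and contralateral side C the cycle starting at a
#' reference heel strike is partitioned into four half-open intervals:
#' LR = \[R.HS, C.TO), LS = \[C.TO, C.HS), PSw = \[C.HS, R.TO),
#' Sw = \[R.TO, next R.HS). Only complete chains are labeled; samples before
#' the first and after the last complete chain stay UNLABELED (-1).
#'
#' @param events_left,events_right `gait_events` (or data frames with
#'   `type`/`index`), each satisfying HS/TO alternation.
#' @param n_samples series length; must exceed the largest event index.
#' @param reference_side `"right"` (default) or `"left"` — the leg whose
#'   cycle the labels describe.
#' @return a `phase_sequence`: integer vector of length `n_samples` with
#'   values in \{-1, 0, 1, 2, 3\} and attribute `reference_side`.
#' @export
label_phases <- function(events_left, events_right, n_samples,
                         reference_side = c("right", "left")) {
  reference_side <- match.arg(reference_side)
  validate_events(events_left, "left events")
  validate_events(events_right, "right events")
  mx <- suppressWarnings(max(c(events_left$index, events_right$index, -1L)))
  if (n_samples <= mx) stop("n_samples must exceed the largest event index", call. = FALSE)
  ref <- if (reference_side == "right") events_right else events_left
  con <- if (reference_side == "right") events_left else events_right
  r_hs <- ref$index[ref$type == "HS"]
  r_to <- ref$index[ref$type == "TO"]
  c_hs <- con$index[con$type == "HS"]
  c_to <- con$index[con$type == "TO"]
  labels <- rep(-1L, n_samples)
  any_labeled <- FALSE
  for (h in r_hs) {
    h2 <- next_after(r_hs, h)          # end of this reference cycle
    if (is.na(h2)) break               # trailing incomplete cycle
    cto <- next_after(c_to, h)
    chs <- if (is.na(cto)) NA_integer_ else next_after(c_hs, cto)
    rto <- if (is.na(chs)) NA_integer_ else next_after(r_to, chs)
    if (anyNA(c(cto, chs, rto))) break # events exhausted: boundary cycle
    early_to <- next_after(r_to, h)
    ok <- cto > h && chs > cto && rto > chs && h2 > rto && early_to > chs
    if (!ok) {
      if (any_labeled) {
        stop(sprintf("labeling error: events interleave out of LR/LS/PSw/Sw order in the reference cycle [%d, %d)", h, h2),
             call. = FALSE)
      }
      next                             # leading cycle without a usable chain
    }
    # 0-based half-open intervals -> 1-based R index ranges
    labels[(h + 1L):cto] <- phase_codes[["LR"]]
    labels[(cto + 1L):chs] <- phase_codes[["LS"]]
    labels[(chs + 1L):rto] <- phase_codes[["PSw"]]
    labels[(rto + 1L):h2] <- phase_codes[["Sw"]]
    any_labeled <- TRUE
  }
  structure(labels, reference_side = reference_side, class = "phase_sequence")
}

#' Summarize phase durations of a labeled sequence
#'
#' Durations are measured over contiguous runs of each label; UNLABELED
#' samples are excluded.
#'
#' @param phases a `phase_sequence` (or integer vector with codes -1..3).
#' @param fs sampling rate in Hz.
#' @return data frame with one row per phase present: `phase`, `n_runs`,
#'   `mean_s`, `sd_s` (sd is 0 for a single run). Empty if nothing labeled.
#' @export
phase_duration_summary <- function(phases, fs) {
  r <- rle(as.integer(phases))
  keep <- r$values >= 0L
  if (!any(keep)) {
    return(data.frame(phase = character(), n_runs = integer(),
                      mean_s = numeric(), sd_s = numeric()))
  }
  vals <- r$values[keep]
  lens <- r$lengths[keep] / fs
  out <- do.call(rbind, lapply(sort(unique(vals)), function(v) {
    li <- lens[vals == v]
    data.frame(phase = phase_names[v + 1L], n_runs = length(li),
               mean_s = mean(li), sd_s = if (length(li) > 1L) stats::sd(li) else 0)
  }))
  rownames(out) <- NULL
  out
}
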