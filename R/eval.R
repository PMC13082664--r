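# Evaluation: confusion matrices (counts and row-normalized percentages),
# overall accuracy and macro-averaged precision / recall / F1, all in %.

#' Confusion matrix of phase predictions
#'
#' @param y_true,y_pred integer labels in 0..3 (codes of [phase_codes]).
#' @return 4 x 4 integer matrix of counts, rows = actual class, columns =
#'   predicted class, in LR, LS, PSw, Sw order.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length", call. = FALSE)
  if (!all(c(y_true, y_pred) %in% 0:3)) {
    stop("labels must be phase codes in 0..3", call. = FALSE)
  }
  m <- table(factor(y_true, levels = 0:3), factor(y_pred, levels = 0:3))
  m <- matrix(as.integer(m), 4L, 4L, dimnames = list(actual = phase_names,
                                                     predicted = phase_names))
  m
}

#' Row-normalize a confusion matrix to percentages
#'
#' @param counts square count matrix.
#' @return matrix of row percentages (each nonempty row sums to 100);
#'   empty rows are all `NaN`.
#' @export
row_normalize <- function(counts) {
  rs <- rowSums(counts)
  sweep(counts, 1L, rs, "/") * 100
}

#' Accuracy and macro-averaged precision / recall / F1 from counts
#'
#' Per-class recall is `diag / rowsum`, precision `diag / colsum`, F1 their
#' harmonic mean; macro values are unweighted means over the classes for
#' which the quantity is defined (a class never predicted has undefined
#' precision and is excluded with a warning; an absent class has undefined
#' recall). All values are percentages.
#'
#' @param counts 4 x 4 confusion count matrix (rows = actual).
#' @return list with `acc`, `macro_pr`, `macro_rc`, `macro_f1` and a
#'   `per_class` data frame.
#' @export
macro_metrics <- function(counts) {
  counts <- as.matrix(counts)
  total <- sum(counts)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  d <- diag(counts)
  rs <- rowSums(counts)
  cs <- colSums(counts)
  rc <- ifelse(rs > 0, d / rs, NA_real_) * 100
  pr <- ifelse(cs > 0, d / cs, NA_real_) * 100
  if (any(cs == 0 & rs > 0)) {
    warning("class(es) never predicted: precision undefined, excluded from macro mean: ",
            paste(rownames(counts)[cs == 0 & rs > 0], collapse = ", "))
  }
  f1 <- ifelse(!is.na(pr) & !is.na(rc) & (pr + rc) > 0, 2 * pr * rc / (pr + rc), NA_real_)
  list(acc = sum(d) / total * 100,
       macro_pr = mean(pr, na.rm = TRUE),
       macro_rc = mean(rc, na.rm = TRUE),
       macro_f1 = mean(f1, na.rm = TRUE),
       per_class = data.frame(phase = rownames(counts) %||% phase_names,
                              precision = pr, recall = rc, f1 = f1,
                              support = as.integer(rs)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Macro recall from a row-normalized confusion matrix
#'
#' Row-normalized rows are per-class recall distributions, so macro recall
#' is simply the mean of the diagonal — independent of class supports.
#'
#' @param row_pct row-normalized (percent) confusion matrix.
#' @return macro recall in %.
#' @export
macro_recall_from_rowpct <- function(row_pct) {
  mean(diag(as.matrix(row_pct)))
}

#' Full evaluation report for a set of predictions
#'
#' @param y_true,y_pred integer labels in 0..3.
#' @return an `eval_report`: confusion counts, row-normalized percentages,
#'   accuracy and macro precision / recall / F1 (all in %), and the
#'   per-class table.
#' @export
eval_report <- function(y_true, y_pred) {
  counts <- confusion_matrix(y_true, y_pred)
  mm <- macro_metrics(counts)
  structure(list(confusion_counts = counts,
                 confusion_row_pct = row_normalize(counts),
                 acc = mm$acc, macro_pr = mm$macro_pr, macro_rc = mm$macro_rc,
                 macro_f1 = mm$macro_f1, per_class = mm$per_class,
                 n = length(y_true)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d\n", x$n))
  cat(sprintf("  ACC %.2f%%  macro PR %.2f%%  RC %.2f%%  F1 %.2f%%\n",
              x$acc, x$macro_pr, x$macro_rc, x$macro_f1))
  cat("  confusion (row %):\n")
  print(round(x$confusion_row_pct, 2))
  invisible(x)
}

#' Evaluate a trained model on a window set
#'
#' @param model a trained `gait_model`.
#' @param windows a `window_set` with targets.
#' @return an [eval_report()].
#' @export
evaluate_model <- function(model, windows) {
  pred <- predict(model, windows)
  eval_report(windows$targets, pred$labels)
}
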