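# Diagnostic classification metrics for the binary melanoma task and
# summary statistics over repeated stochastic optimizer runs.

#' Confusion counts for a binary classifier
#'
#' Tallies the 2x2 confusion table with class 1 as the positive
#' (melanoma) class.
#'
#' @param predicted,actual Binary (0/1) vectors of equal length.
#' @return An object of class `confusion_counts` with integer fields
#'   `tp`, `tn`, `fp`, `fn`.
#' @examples
#' confusion(c(1, 0, 1, 0, 1), c(1, 1, 0, 0, 1))
#' @export
confusion <- function(predicted, actual) {
  predicted <- as.integer(predicted)
  actual <- as.integer(actual)
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have the same length")
  }
  if (length(predicted) < 1L) stop("empty prediction vector")
  if (!all(predicted %in% c(0L, 1L)) || !all(actual %in% c(0L, 1L))) {
    stop("predicted and actual must be binary (0/1)")
  }
  structure(
    list(
      tp = sum(predicted == 1L & actual == 1L),
      tn = sum(predicted == 0L & actual == 0L),
      fp = sum(predicted == 1L & actual == 0L),
      fn = sum(predicted == 0L & actual == 1L)
    ),
    class = "confusion_counts"
  )
}

#' Construct confusion counts directly
#'
#' @param tp,tn,fp,fn Nonnegative integer counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (sum(counts) < 1) stop("at least one count must be positive")
  structure(lapply(as.list(counts), as.integer), class = "confusion_counts")
}

.safe_div <- function(num, den) {
  if (!is.finite(den) || den == 0) NA_real_ else num / den
}

#' Diagnostic metric suite
#'
#' Computes the seven diagnostic metrics used to report binary melanoma
#' screening performance: accuracy (ACC), sensitivity (SNS, recall on the
#' positive class), specificity (SPC), an F-score defined as the harmonic
#' mean of SPC and SNS, the Dice coefficient `2TP / (2TP + FP + FN)`,
#' positive predictive value (PPV) and negative predictive value (NPV).
#' Any metric with a zero denominator is returned as `NA` rather than 0.
#'
#' Note two deliberate conventions: the F-score here is the SPC--SNS harmonic
#' mean (not the conventional F1 over precision/recall), and `strict_literal
#' = TRUE` switches the accuracy denominator to `FP + TP + TP + FN`, an
#' alternative (non-standard) form kept for auditability; the default uses
#' the standard `TP + TN + FP + FN`.
#'
#' @param counts A `confusion_counts` object.
#' @param strict_literal Logical; use the non-standard accuracy denominator.
#' @return An object of class `metrics_report`: a list with numeric fields
#'   `acc`, `sns`, `spc`, `fscore`, `dice`, `ppv`, `npv` (each in \[0, 1\]
#'   or `NA`).
#' @examples
#' compute_metrics(confusion_counts(tp = 3, tn = 5, fp = 1, fn = 1))
#' @export
compute_metrics <- function(counts, strict_literal = FALSE) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  acc_den <- if (strict_literal) fp + tp + tp + fn else tp + tn + fp + fn
  acc <- .safe_div(tp + tn, acc_den)
  sns <- .safe_div(tp, tp + fn)
  spc <- .safe_div(tn, fp + tn)
  ppv <- .safe_div(tp, tp + fp)
  npv <- .safe_div(tn, tn + fn)
  dice <- .safe_div(2 * tp, fp + tp + tp + fn)
  fscore <- if (is.na(spc) || is.na(sns)) {
    NA_real_
  } else {
    .safe_div(2 * spc * sns, spc + sns)
  }
  structure(
    list(acc = acc, sns = sns, spc = spc, fscore = fscore,
         dice = dice, ppv = ppv, npv = npv),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  vals <- unlist(x)
  cat("Diagnostic metrics:\n")
  for (nm in names(vals)) {
    cat(sprintf("  %-6s %s\n", nm,
                ifelse(is.na(vals[[nm]]), "undefined",
                       format(vals[[nm]], digits = 6))))
  }
  invisible(x)
}

#' Summary statistics over repeated runs
#'
#' Aggregates the fitness values of independent optimizer runs: the best
#' (minimum), worst (maximum) and mean fitness, and the sample standard
#' deviation (denominator m - 1). Optionally records the best accuracy over
#' a parallel accuracy sequence.
#'
#' @param values Numeric vector of fitness values, length >= 1 (>= 2 for a
#'   defined standard deviation; with a single value `std` is `NA` and the
#'   result is flagged `reduced`).
#' @param acc_values Optional numeric vector of per-run accuracies; its
#'   maximum is reported as `best_acc`.
#' @return An object of class `run_stats`: `fit_avg`, `std`, `fit_best`,
#'   `fit_worst`, `best_acc` (or `NA`), `m` (number of values), `values`,
#'   `reduced`.
#' @examples
#' run_statistics(c(0.1, 0.2, 0.3))
#' @export
run_statistics <- function(values, acc_values = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("run_statistics requires at least one value")
  if (any(!is.finite(values))) stop("fitness values must be finite")
  m <- length(values)
  reduced <- m < 2L
  structure(
    list(
      fit_avg = mean(values),
      std = if (reduced) NA_real_ else stats::sd(values),
      fit_best = min(values),
      fit_worst = max(values),
      best_acc = if (is.null(acc_values)) NA_real_ else max(as.numeric(acc_values)),
      m = m,
      values = values,
      reduced = reduced
    ),
    class = "run_stats"
  )
}

#' @export
print.run_stats <- function(x, ...) {
  cat(sprintf(
    "Run statistics over m = %d runs:\n  fit_avg %.6g  std %s  fit_best %.6g  fit_worst %.6g\n",
    x$m, x$fit_avg, ifelse(is.na(x$std), "NA", format(x$std, digits = 6)),
    x$fit_best, x$fit_worst
  ))
  if (!is.na(x$best_acc)) cat(sprintf("  best_acc %.6g\n", x$best_acc))
  invisible(x)
}
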