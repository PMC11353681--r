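# Confusion-matrix classification report: per-class precision/recall/F1/
# support, accuracy, macro and support-weighted averages, one-vs-rest
# TPR/FPR. Rounding happens only at display time (2 decimals, half away
# from zero).

#' Confusion matrix for a binary task
#'
#' `counts[i, j]` is the number of samples with true class `i-1` predicted
#' as class `j-1` (rows = truth, columns = prediction).
#'
#' @param y_true,y_pred Equal-length binary vectors.
#' @return A 2x2 integer matrix of class `confusion_matrix` with dimnames
#'   `true` x `pred`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop("values must be binary (0/1)")
  cm <- matrix(0L, 2, 2,
               dimnames = list(true = c("0", "1"), pred = c("0", "1")))
  for (i in 0:1) for (j in 0:1)
    cm[i + 1L, j + 1L] <- sum(y_true == i & y_pred == j)
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Confusion matrix from explicit counts
#'
#' @param counts 2x2 matrix of nonnegative counts, rows = true class.
#' @return A `confusion_matrix`.
#' @export
confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("counts must be 2x2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(true = c("0", "1"), pred = c("0", "1"))
  structure(counts, class = c("confusion_matrix", "matrix"))
}

# round half away from zero (display convention)
.round_half_away <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Classification report from a confusion matrix
#'
#' For each class k: precision = TP_k / predicted_k, recall = TP_k /
#' support_k, F1 = harmonic mean, TPR_k = recall_k and the one-vs-rest
#' FPR_k = FP_k / (n - support_k). Macro averages are unweighted means,
#' weighted averages are support-weighted; for a binary task the weighted
#' recall equals the accuracy exactly. Zero-denominator rates are reported
#' as 0 and flagged.
#'
#' @param cm A `confusion_matrix`.
#' @return An object of class `class_report`: list with `per_class`
#'   (data.frame: class, precision, recall, f1, support, tpr, fpr),
#'   `accuracy`, `macro`, `weighted`, `n`, `zero_denominator`.
#' @examples
#' class_report(confusion_matrix(matrix(c(24, 34, 18, 80), 2, 2)))
#' @export
class_report <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- sum(cm)
  if (n == 0L) stop("empty confusion matrix")
  support <- rowSums(cm)
  predicted <- colSums(cm)
  tp <- diag(cm)
  zero_flag <- FALSE
  safe_div <- function(num, den) {
    out <- ifelse(den > 0, num / ifelse(den > 0, den, 1), 0)
    if (any(den == 0)) zero_flag <<- TRUE
    out
  }
  precision <- safe_div(tp, predicted)
  recall <- safe_div(tp, support)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  fp <- predicted - tp
  fpr <- safe_div(fp, n - support)
  accuracy <- sum(tp) / n
  per_class <- data.frame(class = 0:1, precision = precision, recall = recall,
                          f1 = f1, support = as.integer(support),
                          tpr = recall, fpr = fpr, row.names = NULL)
  wmean <- function(x) sum(x * support) / n
  structure(list(per_class = per_class,
                 accuracy = accuracy,
                 macro = list(precision = mean(precision),
                              recall = mean(recall), f1 = mean(f1)),
                 weighted = list(precision = wmean(precision),
                                 recall = wmean(recall), f1 = wmean(f1)),
                 n = as.integer(n),
                 zero_denominator = zero_flag),
            class = "class_report")
}

#' Format a classification report as an aligned text table
#'
#' Per-class rows, accuracy, macro and weighted averages, then one-vs-rest
#' TPR/FPR rows; values displayed at 2 decimals (half away from zero).
#'
#' @param report A `class_report`.
#' @return Character vector of table lines.
#' @export
format_report <- function(report) {
  r2 <- function(x) sprintf("%.2f", .round_half_away(x))
  pc <- report$per_class
  lines <- c(
    sprintf("%-12s %9s %9s %9s %9s", "", "precision", "recall", "f1-score",
            "support"),
    sprintf("%-12s %9s %9s %9s %9d", "0", r2(pc$precision[1]),
            r2(pc$recall[1]), r2(pc$f1[1]), pc$support[1]),
    sprintf("%-12s %9s %9s %9s %9d", "1", r2(pc$precision[2]),
            r2(pc$recall[2]), r2(pc$f1[2]), pc$support[2]),
    sprintf("%-12s %9s %9s %9s %9d", "accuracy", "", "",
            r2(report$accuracy), report$n),
    sprintf("%-12s %9s %9s %9s %9d", "macro avg", r2(report$macro$precision),
            r2(report$macro$recall), r2(report$macro$f1), report$n),
    sprintf("%-12s %9s %9s %9s %9d", "weighted avg",
            r2(report$weighted$precision), r2(report$weighted$recall),
            r2(report$weighted$f1), report$n),
    sprintf("%-12s %9s %9s", "TPR", r2(pc$tpr[1]), r2(pc$tpr[2])),
    sprintf("%-12s %9s %9s", "FPR", r2(pc$fpr[1]), r2(pc$fpr[2]))
  )
  lines
}

#' @export
print.class_report <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}

#' Serialize a classification report to JSON
#'
#' @param report A `class_report`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
report_to_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), digits = NA, auto_unbox = TRUE,
                         dataframe = "rows")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Reconstruct a binary confusion matrix from recalls and supports
#'
#' With TP_k = round(recall_k * support_k), the off-diagonal of row k is
#' support_k - TP_k. Lets a printed report (recalls + supports) be turned
#' back into counts.
#'
#' @param recalls Length-2 per-class recalls.
#' @param supports Length-2 per-class supports.
#' @return A `confusion_matrix`.
#' @examples
#' reconstruct_confusion(c(0.57, 0.70), c(42, 114))
#' @export
reconstruct_confusion <- function(recalls, supports) {
  if (length(recalls) != 2L || length(supports) != 2L)
    stop("binary task: recalls and supports must have length 2")
  tp <- round(recalls * supports)
  if (any(tp < 0) || any(tp > supports)) stop("infeasible counts")
  confusion_matrix(matrix(c(tp[1], supports[1] - tp[1],
                            supports[2] - tp[2], tp[2]),
                          2, 2, byrow = TRUE))
}
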