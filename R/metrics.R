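# Evaluation metrics: accuracy, Cohen's kappa from the confusion matrix,
# and the across-subject standard deviation of accuracies.

#' Confusion matrix
#'
#' @param truth,pred integer class vectors (0-based or factor-like, same
#'   coding).
#' @param n_classes number of classes c (default 4).
#' @return c x c integer matrix, true classes in rows, predictions in columns.
#' @export
confusion_matrix <- function(truth, pred, n_classes = 4L) {
  stopifnot(length(truth) == length(pred))
  lv <- seq_len(n_classes) - 1L
  as.matrix(table(factor(truth, levels = lv), factor(pred, levels = lv)))
}

#' Cohen's kappa from a confusion matrix
#'
#' `kappa = (P0 - Pe) / (1 - Pe)` with observed agreement `P0` (the accuracy)
#' and chance agreement `Pe = sum_i x_i * P_i / N^2`, where `x_i` and `P_i`
#' are the true and predicted counts of class i. The degenerate case
#' `Pe = 1, P0 = 1` (all mass on one agreeing class) returns 1; `Pe = 1` with
#' imperfect agreement is undefined and raises an error.
#'
#' @param cm square count matrix (true x predicted).
#' @return kappa in [-1, 1].
#' @export
kappa_score <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n <= 0) stop("empty confusion matrix")
  p0 <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-12) {
    if (abs(1 - p0) < 1e-12) return(1)
    stop("kappa undefined: chance agreement is 1 with imperfect agreement")
  }
  (p0 - pe) / (1 - pe)
}

#' Across-subject standard deviation of accuracies
#'
#' Sample standard deviation (divide by N - 1) of per-subject accuracy rates.
#'
#' @param per_subject_acc numeric vector, one accuracy per subject (N >= 2).
#' @export
accuracy_sd <- function(per_subject_acc) {
  if (length(per_subject_acc) < 2)
    stop("standard deviation requires at least 2 subjects")
  stats::sd(per_subject_acc)
}

#' Categorical cross-entropy
#'
#' `L = -sum_i y_i log(p_i)` with one-hot truth; for a matrix of per-trial
#' probability rows the mean over trials is returned. Zero probabilities at
#' the true class are clamped at `eps` before the log.
#'
#' @param probabilities probability vector over classes, or trials x classes
#'   matrix with rows summing to 1.
#' @param true_label 0-based class index (scalar or per-trial vector).
#' @param eps clamp for log(0).
#' @export
cross_entropy <- function(probabilities, true_label, eps = 1e-12) {
  if (is.null(dim(probabilities)))
    probabilities <- matrix(probabilities, nrow = 1L)
  stopifnot(nrow(probabilities) == length(true_label))
  p <- probabilities[cbind(seq_len(nrow(probabilities)),
                           as.integer(true_label) + 1L)]
  mean(-log(pmax(p, eps)))
}

#' Per-subject metrics report
#'
#' @param per_subject data.frame with columns `subject`, `accuracy`, `kappa`.
#' @param confusions optional named list of confusion matrices.
#' @export
metrics_report <- function(per_subject, confusions = NULL) {
  stopifnot(all(c("subject", "accuracy", "kappa") %in% names(per_subject)))
  structure(list(
    per_subject = per_subject,
    mean_accuracy = mean(per_subject$accuracy),
    mean_kappa = mean(per_subject$kappa),
    sd_accuracy = if (nrow(per_subject) >= 2)
      accuracy_sd(per_subject$accuracy) else NA_real_,
    confusions = confusions), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(x$per_subject, row.names = FALSE)
  cat(sprintf("mean accuracy %.2f%%  mean kappa %.3f  SD %s\n",
              100 * x$mean_accuracy, x$mean_kappa,
              if (is.na(x$sd_accuracy)) "n/a (single subject)"
              else sprintf("%.2f", 100 * x$sd_accuracy)))
  invisible(x)
}
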