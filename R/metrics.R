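# Nine-metric classification report computed from the confusion matrix.

#' Nine-metric classification report
#'
#' Computes accuracy, recall, precision, F1, Jaccard, the coefficient of
#' determination on the integer-coded labels, the multiclass Matthews
#' correlation coefficient, Cohen's kappa, and the Hamming loss.
#'
#' Per-class metrics (precision, recall, F1, Jaccard) are averaged per
#' `averaging`: `macro` (unweighted class mean), `weighted` (class mean
#' weighted by true-class support), or `micro` (global counts). A class with
#' an empty denominator contributes 0. MCC uses the multiclass
#' generalization from the confusion matrix; kappa is
#' `(p_o - p_e)/(1 - p_e)` and degenerates to 0 (with a warning) when chance
#' agreement is 1. R-squared on class labels is statistically odd but part
#' of the reported battery; it is computed literally on the integer codes,
#' and defined as 1 for a perfect prediction (0 otherwise) when the true
#' labels are constant.
#'
#' @param y_true,y_pred equal-length integer label vectors.
#' @param averaging `"macro"` (default), `"micro"` or `"weighted"`.
#' @return An object of class `classification_report`: a list of the nine
#'   scores plus the averaging tag, class count, and a `per_class` data
#'   frame (precision/recall/F1/Jaccard/support per class).
#' @export
classification_report <- function(y_true, y_pred,
                                  averaging = c("macro", "micro", "weighted")) {
  averaging <- match.arg(averaging)
  if (length(y_true) != length(y_pred))
    stop_invalid("y_true and y_pred lengths differ")
  if (!length(y_true)) stop_invalid("need at least one sample")
  classes <- sort(unique(c(y_true, y_pred)))
  if (length(classes) < 2L)
    warning("single-class input: chance-corrected metrics degenerate to 0")
  ft <- factor(y_true, levels = classes)
  fp <- factor(y_pred, levels = classes)
  C <- table(ft, fp)                      # rows = true, cols = predicted
  n <- length(y_true)
  tp <- diag(C)
  fn <- rowSums(C) - tp
  fpv <- colSums(C) - tp
  acc <- sum(tp) / n
  prec_c <- ifelse(tp + fpv > 0, tp / (tp + fpv), 0)
  rec_c <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1_c <- ifelse(prec_c + rec_c > 0, 2 * prec_c * rec_c / (prec_c + rec_c), 0)
  jac_c <- ifelse(tp + fpv + fn > 0, tp / (tp + fpv + fn), 0)
  avg <- switch(averaging,
    macro = function(v, micro) mean(v),
    weighted = function(v, micro) sum(v * rowSums(C)) / n,
    micro = function(v, micro) micro)
  micro_prec <- sum(tp) / max(sum(tp + fpv), 1)
  micro_jac <- sum(tp) / max(sum(tp) + sum(fpv) + sum(fn), 1)
  precision <- avg(prec_c, micro_prec)
  recall <- avg(rec_c, micro_prec)
  f1 <- avg(f1_c, micro_prec)
  jaccard <- avg(jac_c, micro_jac)
  # multiclass MCC from the confusion matrix
  s <- n; c_tr <- sum(tp)
  pk <- colSums(C); tk <- rowSums(C)
  mcc_den <- sqrt(as.numeric(s^2 - sum(pk^2)) * as.numeric(s^2 - sum(tk^2)))
  mcc <- if (mcc_den == 0) 0 else (c_tr * s - sum(pk * tk)) / mcc_den
  pe <- sum(as.numeric(pk) * as.numeric(tk)) / n^2
  kappa <- if (1 - pe == 0) { if (length(classes) > 1L)
    warning("degenerate kappa (chance agreement 1); defined as 0"); 0
  } else (acc - pe) / (1 - pe)
  hamming <- mean(y_true != y_pred)
  ss_tot <- sum((y_true - mean(y_true))^2)
  ss_res <- sum((y_true - y_pred)^2)
  r2 <- if (ss_tot == 0) as.numeric(ss_res == 0) else 1 - ss_res / ss_tot
  structure(list(accuracy = acc, recall = recall, f1 = f1,
                 precision = precision, r2 = r2, mcc = mcc,
                 cohen_kappa = kappa, hamming_loss = hamming,
                 jaccard = jaccard, averaging = averaging,
                 n_classes = length(classes),
                 per_class = data.frame(class = classes,
                                        precision = as.numeric(prec_c),
                                        recall = as.numeric(rec_c),
                                        f1 = as.numeric(f1_c),
                                        jaccard = as.numeric(jac_c),
                                        support = as.numeric(rowSums(C)))),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %d classes, %s averaging\n",
              x$n_classes, x$averaging))
  v <- unlist(x[c("accuracy", "recall", "f1", "precision", "r2", "mcc",
                  "cohen_kappa", "hamming_loss", "jaccard")])
  print(round(v, 4))
  invisible(x)
}

#' Flatten a report to a one-row data frame
#' @param report a [classification_report()].
#' @return One-row data frame with the nine scores and the averaging tag.
#' @export
report_row <- function(report) {
  stopifnot(inherits(report, "classification_report"))
  as.data.frame(report[c("accuracy", "recall", "f1", "precision", "r2",
                         "mcc", "cohen_kappa", "hamming_loss", "jaccard",
                         "averaging", "n_classes")])
}
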