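# Confusion-matrix metrics used as cross-validation fitness and for
# reporting: accuracy, sensitivity, specificity and the Matthews correlation
# coefficient.

#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred Equal-length binary label vectors.
#' @param positive_label Value counted as positive (default `+1`).
#' @return A `confusion_counts` list with integers `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(y_true, y_pred, positive_label = 1) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length")
  }
  if (length(unique(y_true)) > 2L || length(unique(y_pred)) > 2L) {
    stop("labels must be binary")
  }
  tp <- sum(y_true == positive_label & y_pred == positive_label)
  tn <- sum(y_true != positive_label & y_pred != positive_label)
  fp <- sum(y_true != positive_label & y_pred == positive_label)
  fn <- sum(y_true == positive_label & y_pred != positive_label)
  structure(list(TP = as.integer(tp), TN = as.integer(tn),
                 FP = as.integer(fp), FN = as.integer(fn)),
            class = "confusion_counts")
}

#' Accuracy, sensitivity, specificity and MCC from confusion counts
#'
#' `acc = (TP+TN)/(TP+TN+FP+FN)`; `sensitivity = TP/(TP+FN)`;
#' `specificity = TN/(TN+FP)`;
#' `mcc = (TP*TN - FP*FN) / sqrt((TN+FP)(TN+FN)(TP+FN)(TP+FP))`.
#'
#' Degenerate denominators follow a fixed convention so tiny CV folds stay
#' defined: sensitivity (resp. specificity) is 0 with a warning when the fold
#' has no positives (resp. negatives), and MCC is 0 when any factor under the
#' root is 0.
#'
#' @param c A `confusion_counts` or a list with `TP`, `TN`, `FP`, `FN`.
#' @return A `metric_set` list: `acc`, `sensitivity`, `specificity`, `mcc`.
#' @export
compute_metrics <- function(c) {
  tp <- c$TP; tn <- c$TN; fp <- c$FP; fn <- c$FN
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  if (total == 0) stop("no samples: all confusion counts are zero")
  acc <- (tp + tn) / total
  if (tp + fn == 0) {
    warning("no positive samples; sensitivity set to 0")
    sens <- 0
  } else sens <- tp / (tp + fn)
  if (tn + fp == 0) {
    warning("no negative samples; specificity set to 0")
    spec <- 0
  } else spec <- tn / (tn + fp)
  denom2 <- (tn + fp) * (tn + fn) * (tp + fn) * (tp + fp)
  mcc <- if (denom2 == 0) 0 else (tp * tn - fp * fn) / sqrt(denom2)
  structure(list(acc = acc, sensitivity = sens, specificity = spec,
                 mcc = mcc),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("acc %.5f  sensitivity %.5f  specificity %.5f  mcc %.5f\n",
              x$acc, x$sensitivity, x$specificity, x$mcc))
  invisible(x)
}

#' Write a per-fold metric table as delimited text
#'
#' One row per metric with mean, std and the per-fold columns `1#` ... `k#`,
#' mirroring the customary cross-validation report layout.
#'
#' @param fold_metrics List of `metric_set`s, one per fold.
#' @param path Output file.
#' @return The written data frame, invisibly.
#' @export
write_metric_table <- function(fold_metrics, path) {
  metrics <- c("acc", "sensitivity", "specificity", "mcc")
  rows <- lapply(metrics, function(m) {
    vals <- vapply(fold_metrics, function(f) f[[m]], numeric(1))
    c(mean = mean(vals), std = stats::sd(vals), vals)
  })
  tab <- do.call(rbind, rows)
  colnames(tab) <- c("Mean", "Std", paste0(seq_along(fold_metrics), "#"))
  df <- data.frame(Indicator = metrics, tab, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
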