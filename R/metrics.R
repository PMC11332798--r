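#' Confusion matrix of predictions
#'
#' Rows are actual classes, columns predicted classes.
#'
#' @param actual,predicted integer labels `0 .. n_classes-1`.
#' @param n_classes number of classes.
#' @return `n_classes x n_classes` count matrix.
#' @export
confusion_matrix <- function(actual, predicted, n_classes = 4) {
  m <- matrix(0L, n_classes, n_classes,
              dimnames = list(actual = wbc_classes()[1:n_classes],
                              predicted = wbc_classes()[1:n_classes]))
  for (i in seq_along(actual))
    m[actual[i] + 1, predicted[i] + 1] <- m[actual[i] + 1, predicted[i] + 1] + 1L
  m
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is the diagonal sum over the total; per-class one-vs-rest
#' precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and `F1 = 2PR/(P+R)`; macro
#' averages are unweighted means. A zero denominator yields 0 and raises the
#' `zero_division` flag rather than NaN.
#'
#' @param confusion square count matrix, rows actual, columns predicted.
#' @return object of class `wbc_metrics`: `accuracy`, `per_class` data
#'   frame, `macro_precision`, `macro_recall`, `macro_f1`, `zero_division`.
#' @export
compute_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0)) stop_wbc("wbc_metric_error", "negative counts")
  total <- sum(confusion)
  if (total == 0) stop_wbc("wbc_metric_error", "all-zero confusion matrix")
  K <- nrow(confusion)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  flag <- FALSE
  safe_div <- function(a, b) {
    out <- ifelse(b > 0, a / ifelse(b > 0, b, 1), 0)
    if (any(b == 0)) flag <<- TRUE
    out
  }
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  per_class <- data.frame(class = rownames(confusion) %||% paste0("C", seq_len(K) - 1),
                          precision = precision, recall = recall, f1 = f1,
                          support = rowSums(confusion), row.names = NULL)
  structure(list(accuracy = sum(tp) / total, per_class = per_class,
                 macro_precision = mean(precision), macro_recall = mean(recall),
                 macro_f1 = mean(f1), zero_division = flag,
                 confusion = confusion),
            class = "wbc_metrics")
}

#' @export
print.wbc_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro P %.4f R %.4f F1 %.4f%s\n", x$accuracy,
              x$macro_precision, x$macro_recall, x$macro_f1,
              if (x$zero_division) " [zero-division flagged]" else ""))
  print(x$per_class, row.names = FALSE, digits = 4)
  invisible(x)
}

#' One-vs-rest ROC curves and AUC
#'
#' For each class, sweeps the score thresholds (tied scores grouped, which
#' makes the trapezoid area equal to the midrank Mann-Whitney statistic)
#' and integrates TPR over FPR by the trapezoid rule; the macro average is
#' the unweighted mean over classes.
#'
#' @param scores `N x K` matrix of class scores (e.g. softmax rows).
#' @param labels integer labels `0 .. K-1`.
#' @return object of class `wbc_roc`: `auc` (per class), `macro_auc`,
#'   `curves` (per-class data frames with `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  if (!is.matrix(scores)) stop_wbc("wbc_shape_error", "scores must be a matrix")
  K <- ncol(scores)
  if (length(unique(labels)) < 2)
    stop_wbc("wbc_metric_error", "ROC needs at least two classes in labels")
  auc <- numeric(K)
  curves <- vector("list", K)
  for (k in seq_len(K)) {
    pos <- labels == (k - 1)
    P <- sum(pos); Nn <- sum(!pos)
    if (P == 0 || Nn == 0) {
      auc[k] <- NA_real_
      curves[[k]] <- data.frame(fpr = c(0, 1), tpr = c(0, 1))
      next
    }
    s <- scores[, k]
    o <- order(s, decreasing = TRUE)
    sp <- s[o]; lp <- pos[o]
    ends <- c(which(diff(sp) != 0), length(sp))  # last index of each tie block
    tpr <- c(0, cumsum(lp)[ends] / P)
    fpr <- c(0, cumsum(!lp)[ends] / Nn)
    auc[k] <- sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
    curves[[k]] <- data.frame(fpr = fpr, tpr = tpr)
  }
  names(auc) <- names(curves) <- wbc_classes()[1:K]
  structure(list(auc = auc, macro_auc = mean(auc, na.rm = TRUE),
                 curves = curves),
            class = "wbc_roc")
}

#' @export
print.wbc_roc <- function(x, ...) {
  cat("per-class AUC:", paste(sprintf("%s %.4f", names(x$auc), x$auc),
                              collapse = ", "), "\n")
  cat(sprintf("macro-average AUC: %.4f\n", x$macro_auc))
  invisible(x)
}

#' @export
plot.wbc_roc <- function(x, ...) {
  cols <- c("firebrick", "steelblue", "darkgreen", "orange")
  graphics::plot(0:1, 0:1, type = "l", lty = 3, col = "grey",
                 xlab = "false positive rate", ylab = "true positive rate", ...)
  for (k in seq_along(x$curves))
    graphics::lines(x$curves[[k]]$fpr, x$curves[[k]]$tpr,
                    col = cols[(k - 1) %% 4 + 1])
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("%s (AUC %.3f)", names(x$auc), x$auc),
                   col = cols[(seq_along(x$auc) - 1) %% 4 + 1], lty = 1)
  invisible(x)
}

#' Evaluate a fitted model on a test set
#'
#' @param model a `wbc_net` (or raw `wbc_network`).
#' @param x `H x W x C x N` test inputs in `[0, 1]`.
#' @param y integer test labels.
#' @return object of class `wbc_eval_report`: `confusion`, `metrics`
#'   ([compute_metrics()]), `roc` ([roc_auc()]), `probs`, `predicted`.
#' @export
evaluate_network <- function(model, x, y) {
  probs <- if (inherits(model, "wbc_net")) predict(model, x, type = "prob")
           else network_predict_batched(model, x)
  pred <- max.col(probs, ties.method = "first") - 1L
  K <- ncol(probs)
  cm <- confusion_matrix(y, pred, n_classes = K)
  structure(list(confusion = cm, metrics = compute_metrics(cm),
                 roc = roc_auc(probs, y), probs = probs, predicted = pred),
            class = "wbc_eval_report")
}

#' @export
print.wbc_eval_report <- function(x, ...) {
  cat("confusion matrix (rows = actual, columns = predicted):\n")
  print(x$confusion)
  print(x$metrics)
  print(x$roc)
  invisible(x)
}
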