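#' Softmax activation
#'
#' `f(s)_i = exp(s_i) / sum_j exp(s_j)`, computed with max-shift
#' stabilization so large scores cannot overflow.
#'
#' @param scores numeric vector, or matrix with one score row per sample.
#' @return object of the same shape whose (row) entries are nonnegative and
#'   sum to 1.
#' @export
softmax <- function(scores) {
  if (is.matrix(scores)) {
    m <- apply(scores, 1, max)
    e <- exp(scores - m)
    e / rowSums(e)
  } else {
    e <- exp(scores - max(scores))
    e / sum(e)
  }
}

#' Mean cross-entropy of probabilistic predictions
#'
#' The one-hot specialization of categorical cross entropy: the mean over
#' the batch of `-log q(true class)`, for integer labels. Numerically
#' identical to the "sparse" variant over integer labels.
#'
#' @param probabilities `N x K` matrix of class probabilities (rows on the
#'   simplex) or a single length-`K` vector.
#' @param labels integer class ids in `[0, K)`, one per row.
#' @param tol tolerance for the row-sum check.
#' @return mean loss (a single number).
#' @export
cross_entropy_loss <- function(probabilities, labels, tol = 1e-6) {
  if (!is.matrix(probabilities)) probabilities <- matrix(probabilities, 1)
  K <- ncol(probabilities)
  if (any(labels < 0 | labels >= K))
    stop_wbc("wbc_label_error", "labels must lie in [0, %d)", K)
  if (any(abs(rowSums(probabilities) - 1) > tol))
    stop_wbc("wbc_config_error", "probability rows must sum to 1")
  if (length(labels) != nrow(probabilities))
    stop_wbc("wbc_shape_error", "one label per probability row required")
  p <- probabilities[cbind(seq_len(nrow(probabilities)), labels + 1)]
  mean(-log(pmax(p, 1e-12)))
}

# fused softmax + cross entropy with the gradient w.r.t. the logits
softmax_ce <- function(logits, labels) {
  p <- softmax(logits)
  n <- nrow(logits)
  loss <- cross_entropy_loss(p, labels)
  d <- p
  d[cbind(seq_len(n), labels + 1)] <- d[cbind(seq_len(n), labels + 1)] - 1
  list(loss = loss, probs = p, dlogits = d / n)
}
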