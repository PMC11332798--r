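#' Stratified split plan
#'
#' @param train,val,test fractions summing to 1.
#' @param stratified split within each class (default) or over the pooled
#'   manifest.
#' @param seed integer seed for the per-class shuffles.
#' @return an object of class `wbc_split_plan`.
#' @export
split_plan <- function(train = 0.70, val = 0.15, test = 0.15,
                       stratified = TRUE, seed = 1) {
  if (abs(train + val + test - 1) > 1e-9)
    stop_wbc("wbc_config_error", "split fractions must sum to 1")
  if (any(c(train, val, test) < 0))
    stop_wbc("wbc_config_error", "split fractions must be nonnegative")
  structure(list(train = train, val = val, test = test,
                 stratified = stratified, seed = seed),
            class = "wbc_split_plan")
}

# largest-remainder allocation of n items to fractions, each nonzero
# fraction guaranteed at least one item
allocate_counts <- function(n, fracs) {
  raw <- n * fracs
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  for (i in which(fracs > 0 & base == 0)) {
    donor <- which.max(base)
    base[donor] <- base[donor] - 1
    base[i] <- 1
  }
  base
}

#' Stratified train/validation/test split of a manifest
#'
#' Partitions the manifest so that each class contributes to each split in
#' the plan's proportions (exact up to rounding); the three parts are
#' disjoint and exhaustive, and the same seed reproduces the same split.
#'
#' @param manifest data frame with at least a `label` column.
#' @param plan a [split_plan()].
#' @return list of three manifests: `train`, `val`, `test`.
#' @export
stratified_split <- function(manifest, plan = split_plan()) {
  fracs <- c(plan$train, plan$val, plan$test)
  nz <- sum(fracs > 0)
  groups <- if (plan$stratified) split(seq_len(nrow(manifest)), manifest$label)
            else list(all = seq_len(nrow(manifest)))
  parts <- list(train = integer(0), val = integer(0), test = integer(0))
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    if (length(idx) < nz)
      stop_wbc("wbc_split_error",
               "class %s has %d images, fewer than the %d splits",
               names(groups)[gi], length(idx), nz)
    idx <- with_seed(derive_seed(plan$seed, "split", gi), sample(idx))
    cnt <- allocate_counts(length(idx), fracs)
    parts$train <- c(parts$train, idx[seq_len(cnt[1])])
    parts$val <- c(parts$val, idx[cnt[1] + seq_len(cnt[2])])
    parts$test <- c(parts$test, idx[cnt[1] + cnt[2] + seq_len(cnt[3])])
  }
  lapply(parts, function(i) manifest[sort(i), , drop = FALSE])
}

#' Train the network with mini-batch Nadam
#'
#' Runs the configured number of epochs of shuffled mini-batch training,
#' recording train/validation accuracy and loss per epoch, and keeps the
#' weights of the best validation-accuracy epoch (ties go to the earliest).
#' With the same seed, data and single-threaded numerics the run is fully
#' reproducible.
#'
#' @param net a `wbc_network` from [build_network()].
#' @param x `H x W x C x N` training inputs in `[0, 1]`.
#' @param y integer labels `0 .. n_classes-1`.
#' @param x_val,y_val optional validation data.
#' @param params a [training_params()].
#' @param stop_at_val_acc optional early-stop threshold: training ends after
#'   the first epoch whose validation accuracy reaches this value.
#' @param verbose print one line per epoch.
#' @return an object of class `wbc_net`: list with `network` (final
#'   weights), `best` (best-validation weights), `history` (one row per
#'   epoch), `params`, `classes`.
#' @export
train_network <- function(net, x, y, x_val = NULL, y_val = NULL,
                          params = training_params(), stop_at_val_acc = NULL,
                          verbose = FALSE) {
  if (length(dim(x)) != 4 || dim(x)[4] != length(y))
    stop_wbc("wbc_shape_error", "x must be H x W x C x N with one label per image")
  N <- length(y)
  if (N == 0) stop_wbc("wbc_config_error", "empty training set")
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_acc = numeric(0), val_loss = numeric(0),
                        val_acc = numeric(0))
  best <- list(net = net, val_acc = -Inf, epoch = 0L)
  if (params$epochs == 0)
    return(structure(list(network = net, best = net, history = history,
                          params = params, classes = wbc_classes()),
                     class = "wbc_net"))
  theta <- collect_params(net)
  state <- nadam_init(theta, params)
  for (e in seq_len(params$epochs)) {
    ep_losses <- c(); ep_hits <- 0
    with_seed(derive_seed(params$seed, "epoch", e), {
      perm <- sample(N)
      nb <- ceiling(N / params$batch_size)
      for (b in seq_len(nb)) {
        take <- perm[((b - 1) * params$batch_size + 1):min(b * params$batch_size, N)]
        xb <- x[, , , take, drop = FALSE]
        yb <- y[take]
        fw <- net_forward(net, xb, training = TRUE, keep_caches = TRUE)
        sc <- softmax_ce(fw$out, yb)
        if (!is.finite(sc$loss))
          stop_wbc("wbc_numeric_error", "non-finite loss at epoch %d batch %d", e, b)
        bw <- net_backward(net, fw$caches, sc$dlogits)
        g <- collect_grads(net, bw$grads)[names(theta)]
        st <- nadam_step(theta, g, state)
        theta <- st$params; state <- st$state
        net <- set_params(net, theta)
        net <- apply_run_updates(net, fw$run_updates)
        ep_losses <- c(ep_losses, sc$loss)
        ep_hits <- ep_hits + sum(max.col(sc$probs, ties.method = "first") - 1 == yb)
      }
    })
    va <- NA_real_; vl <- NA_real_
    if (!is.null(x_val)) {
      pv <- network_predict_batched(net, x_val)
      vl <- cross_entropy_loss(pv, y_val)
      va <- mean(max.col(pv, ties.method = "first") - 1 == y_val)
      if (va > best$val_acc) best <- list(net = net, val_acc = va, epoch = e)
    }
    history <- rbind(history, data.frame(epoch = e, train_loss = mean(ep_losses),
                                         train_acc = ep_hits / N,
                                         val_loss = vl, val_acc = va))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f  val_loss %.4f  val_acc %.3f",
                      e, mean(ep_losses), ep_hits / N, vl, va))
    if (!is.null(stop_at_val_acc) && is.finite(va) && va >= stop_at_val_acc) break
  }
  if (!is.finite(best$val_acc)) best$net <- net
  structure(list(network = net, best = best$net, history = history,
                 best_epoch = best$epoch, params = params,
                 classes = wbc_classes()),
            class = "wbc_net")
}

network_predict_batched <- function(net, x, chunk = 64) {
  N <- dim(x)[4]
  out <- NULL
  for (s in seq(1, N, by = chunk)) {
    take <- s:min(s + chunk - 1, N)
    out <- rbind(out, network_predict(net, x[, , , take, drop = FALSE]))
  }
  out
}

#' @export
print.wbc_net <- function(x, ...) {
  cat(sprintf("<wbc_net> trained %d epochs", nrow(x$history)))
  if (nrow(x$history) > 0 && !all(is.na(x$history$val_acc)))
    cat(sprintf("; best val acc %.3f (epoch %d)",
                max(x$history$val_acc, na.rm = TRUE), x$best_epoch))
  cat("\n")
  print(x$network)
  invisible(x)
}

#' @export
summary.wbc_net <- function(object, ...) {
  print(object)
  if (nrow(object$history) > 0) {
    cat("last epochs:\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' Predict classes or probabilities from a fitted model
#'
#' Uses the best-validation-epoch weights.
#'
#' @param object a `wbc_net`.
#' @param newdata `H x W x C x N` array (or single image) in `[0, 1]`.
#' @param type `"prob"` for the probability matrix, `"class"` for integer
#'   labels (argmax, lowest index on ties), `"label"` for class names.
#' @param ... unused.
#' @export
predict.wbc_net <- function(object, newdata,
                            type = c("prob", "class", "label"), ...) {
  type <- match.arg(type)
  if (length(dim(newdata)) == 3) dim(newdata) <- c(dim(newdata), 1)
  p <- network_predict_batched(object$best, newdata)
  colnames(p) <- object$classes[seq_len(ncol(p))]
  switch(type,
         prob = p,
         class = max.col(p, ties.method = "first") - 1L,
         label = object$classes[max.col(p, ties.method = "first")])
}

#' Plot training curves
#'
#' Accuracy and loss per epoch for the training and validation sets.
#'
#' @param x a `wbc_net`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.wbc_net <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0) {
    warning("no training history to plot")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "l", lty = 1,
                    col = c("steelblue", "firebrick"), xlab = "epoch",
                    ylab = "accuracy", ...)
  graphics::legend("bottomright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l", lty = 1,
                    col = c("steelblue", "firebrick"), xlab = "epoch",
                    ylab = "loss", ...)
  invisible(x)
}
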