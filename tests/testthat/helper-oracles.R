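# Independent oracles and shared fixtures. Everything here is deliberately
# naive (double loops, closed forms, subset enumeration) so it cannot share
# a defect with the vectorized implementations it checks.

# sliding-minimum erosion: out-of-image counts as foreground
naive_erode <- function(mask, se) {
  r <- (nrow(se) - 1) / 2
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0L, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    v <- 1L
    for (di in -r:r) for (dj in -r:r) {
      if (se[di + r + 1, dj + r + 1] == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W && mask[ii, jj] == 0) v <- 0L
    }
    out[i, j] <- v
  }
  out
}

# sliding-maximum dilation: out-of-image counts as background
naive_dilate <- function(mask, se) {
  r <- (nrow(se) - 1) / 2
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0L, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    v <- 0L
    for (di in -r:r) for (dj in -r:r) {
      if (se[di + r + 1, dj + r + 1] == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W && mask[ii, jj] == 1) v <- 1L
    }
    out[i, j] <- v
  }
  out
}

# one-vs-rest tallies straight from the definition
naive_metrics <- function(cm) {
  K <- nrow(cm)
  pr <- re <- f1 <- numeric(K)
  for (k in seq_len(K)) {
    tp <- cm[k, k]
    fp <- sum(cm[-k, k])
    fn <- sum(cm[k, -k])
    pr[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    re[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k] <- if (pr[k] + re[k] > 0) 2 * pr[k] * re[k] / (pr[k] + re[k]) else 0
  }
  list(accuracy = sum(diag(cm)) / sum(cm), precision = pr, recall = re, f1 = f1)
}

# AUC as the normalized Mann-Whitney U statistic with midranks
mw_auc <- function(scores, pos) {
  rk <- rank(scores)
  P <- sum(pos); N <- sum(!pos)
  (sum(rk[pos]) - P * (P + 1) / 2) / (P * N)
}

# brute-force Shapley values by subset enumeration
enum_shapley <- function(f, M) {
  phi <- numeric(M)
  subsets <- as.matrix(expand.grid(rep(list(0:1), M)))
  for (i in seq_len(M)) {
    tot <- 0
    for (r in seq_len(nrow(subsets))) {
      z <- subsets[r, ]
      if (z[i] == 1) next
      s <- sum(z)
      wgt <- factorial(s) * factorial(M - s - 1) / factorial(M)
      zi <- z; zi[i] <- 1
      tot <- tot + wgt * (f(zi) - f(z))
    }
    phi[i] <- tot
  }
  phi
}

# a tiny network whose class-0 logit is the spatial mean of feature map 1
# of its only conv block (linear head, no pooling)
toy_mean_net <- function(hw = 8, n_maps = 4, seed = 1) {
  spec <- network_spec(input_shape = c(hw, hw, 3),
                       blocks = list(block_spec(1, n_maps, "standard",
                                                batch_norm = FALSE, pool = FALSE)),
                       head_units = integer(0), head_dropout = numeric(0),
                       n_classes = 4)
  net <- build_network(spec, seed = seed)
  L <- length(net$layers)
  W <- matrix(0, n_maps * hw * hw, 4)
  W[seq_len(hw * hw), 1] <- 1 / (hw * hw)
  net$layers[[L]]$W <- W
  net$layers[[L]]$b <- rep(0, 4)
  net
}

# black box that is a fixed linear function of superpixel indicators;
# detects on/off by comparing one pixel per segment against the baseline
planted_linear_box <- function(segs, base, w, offset = 0.5, scale = 10) {
  M <- max(segs)
  probe <- t(vapply(seq_len(M), function(s) {
    which(segs == s, arr.ind = TRUE)[1, ]
  }, numeric(2)))
  function(batch) {
    N <- dim(batch)[4]
    out <- matrix(0, N, 4)
    for (j in seq_len(N)) {
      z <- vapply(seq_len(M), function(s) {
        any(abs(batch[probe[s, 1], probe[s, 2], , j] -
                base[probe[s, 1], probe[s, 2], ]) > 1e-12)
      }, logical(1))
      out[j, 1] <- offset + sum(w * z) / scale
    }
    out[, 2] <- 1 - out[, 1]
    out
  }
}

# ground-truth nucleus box mapped into crop coordinates of a segmentation
gt_box_in_crop <- function(truth, seg, pad = 10, target = 48) {
  gt <- truth$nucleus_bbox + pad
  bb <- seg$bbox
  sr <- target / (bb[3] - bb[1])
  sc <- target / (bb[4] - bb[2])
  c(max(0, (gt[1] - bb[1]) * sr), max(0, (gt[2] - bb[2]) * sc),
    min(target, (gt[3] - bb[1]) * sr), min(target, (gt[4] - bb[2]) * sc))
}

# fraction of the top-decile heat pixels that fall inside a box
top_decile_overlap <- function(map, box) {
  thr <- stats::quantile(map, 0.9)
  idx <- which(map >= thr, arr.ind = TRUE)
  inside <- idx[, 1] - 1 >= box[1] & idx[, 1] <= box[3] &
            idx[, 2] - 1 >= box[2] & idx[, 2] <= box[4]
  mean(inside)
}

# --- shared scaled training runs (memoized across test files) -------------
# Conditions of the desk-scale study: 200 synthetic images per class on a
# 120 px canvas, 48 px crops, the scaled three-block network, Nadam with
# learning rate 1e-3, batch 64, at most 30 epochs (early stop once
# validation accuracy reaches 0.95).
.wbc_test_cache <- new.env(parent = emptyenv())

scaled_dataset <- function(n_per_class = 200, data_seed = 101) {
  key <- paste0("ds", n_per_class, "_", data_seed)
  if (is.null(.wbc_test_cache[[key]]))
    .wbc_test_cache[[key]] <- synthetic_cell_dataset(
      n_per_class, smear_spec(image_size = 120),
      pipeline_config(target_size = 48), seed = data_seed)
  .wbc_test_cache[[key]]
}

scaled_training_run <- function(seed, n_per_class = 200, data_seed = 101) {
  key <- paste0("fit", seed, "_", n_per_class, "_", data_seed)
  if (!is.null(.wbc_test_cache[[key]])) return(.wbc_test_cache[[key]])
  ds <- scaled_dataset(n_per_class, data_seed)
  man <- data.frame(idx = seq_along(ds$y), label = ds$y)
  sp <- stratified_split(man, split_plan(seed = seed))
  net <- build_network(scaled_network_spec(48), seed = derive_seed(seed, "init"))
  fit <- train_network(net,
                       ds$x[, , , sp$train$idx, drop = FALSE], ds$y[sp$train$idx],
                       ds$x[, , , sp$val$idx, drop = FALSE], ds$y[sp$val$idx],
                       training_params(learning_rate = 1e-3, batch_size = 64,
                                       epochs = 30, seed = seed),
                       stop_at_val_acc = 0.95)
  res <- list(fit = fit, split = sp, ds = ds)
  .wbc_test_cache[[key]] <- res
  res
}
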