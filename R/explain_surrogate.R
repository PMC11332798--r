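# Perturbation-based explainers over superpixels. Both treat the classifier
# as a black box reached only through `predict_fn`, and both explain the
# target-class probability as a function of which segments are kept (1) or
# replaced by a baseline color (0).

#' Superpixel segmentation plan
#'
#' @param method `"grid"` (regular tiles) or `"slic-like"` (seeded k-means
#'   over position and color features; compact, color-coherent segments,
#'   contiguity not enforced).
#' @param n_segments requested number of segments (`>= 2`; the grid method
#'   may deliver a slightly different count).
#' @param baseline replacement for switched-off segments: `"mean-color"`
#'   (per-image channel means; the default, since a black baseline would
#'   collide with the black background the masking step produces),
#'   `"gray"`, or `"black"`.
#' @return an object of class `wbc_superpixel_plan`.
#' @export
superpixel_plan <- function(method = c("grid", "slic-like"), n_segments = 40,
                            baseline = c("mean-color", "gray", "black")) {
  method <- match.arg(method)
  baseline <- match.arg(baseline)
  if (n_segments < 2) stop_wbc("wbc_config_error", "n_segments must be >= 2")
  structure(list(method = method, n_segments = n_segments, baseline = baseline),
            class = "wbc_superpixel_plan")
}

#' Segment an image into superpixels
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param plan a [superpixel_plan()].
#' @param seed seed for the `"slic-like"` k-means.
#' @return integer `H x W` matrix of segment ids `1 .. M`; every pixel
#'   belongs to exactly one segment.
#' @export
make_superpixels <- function(image, plan = superpixel_plan(), seed = 1) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  if (plan$method == "grid") {
    gr <- max(1, round(sqrt(plan$n_segments * H / W)))
    gc <- max(1, round(plan$n_segments / gr))
    ri <- ceiling(seq_len(H) / H * gr)
    ci <- ceiling(seq_len(W) / W * gc)
    segs <- outer(ri, (ci - 1) * gr, `+`)
  } else {
    sc <- sqrt(plan$n_segments)  # position weight comparable to color
    feats <- cbind(as.vector(row(matrix(0, H, W))) / H * sc,
                   as.vector(col(matrix(0, H, W))) / W * sc,
                   matrix(image, H * W, 3))
    km <- with_seed(seed, stats::kmeans(feats, centers = plan$n_segments,
                                        iter.max = 20, nstart = 1))
    segs <- matrix(km$cluster, H, W)
  }
  ids <- sort(unique(as.vector(segs)))
  matrix(match(segs, ids), H, W)
}

baseline_image <- function(image, plan) {
  d <- dim(image)
  col <- switch(plan$baseline,
                "mean-color" = apply(image, 3, mean),
                "gray" = rep(0.5, 3),
                "black" = rep(0, 3))
  array(rep(col, each = d[1] * d[2]), d)
}

# composite: keep segments with z = 1, replace the rest with the baseline
mask_to_image <- function(image, base, segs, z) {
  keep <- array(z[segs] == 1, dim(image))
  image * keep + base * !keep
}

predict_masked <- function(predict_fn, image, base, segs, Z, chunk = 64) {
  n <- nrow(Z)
  d <- dim(image)
  out <- NULL
  for (s in seq(1, n, by = chunk)) {
    take <- s:min(s + chunk - 1, n)
    batch <- array(0, c(d, length(take)))
    for (j in seq_along(take))
      batch[, , , j] <- mask_to_image(image, base, segs, Z[take[j], ])
    p <- predict_fn(batch)
    if (!is.matrix(p)) p <- matrix(p, nrow = length(take))
    out <- rbind(out, p)
  }
  out
}

#' LIME explanation of one image prediction
#'
#' Fits a locally weighted ridge surrogate: seeded binary on/off vectors
#' over superpixels, perturbed images with off segments set to the baseline
#' color, sample weights `exp(-d^2 / kernel_width^2)` with `d` the cosine
#' distance of the on/off vector from all-ones, and a ridge regression of
#' the target-class probability on the indicators (unpenalized intercept).
#'
#' @param predict_fn function mapping an `H x W x 3 x N` batch in `[0, 1]`
#'   to an `N x K` probability matrix.
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param target_class class id `0 .. K-1`.
#' @param plan a [superpixel_plan()].
#' @param n_samples number of perturbations (`>= n_segments + 2`); the
#'   unperturbed all-ones vector is always included.
#' @param kernel_width locality kernel width on cosine distance.
#' @param ridge penalty on the segment coefficients.
#' @param seed seed for the perturbation draws.
#' @return a `wbc_attribution` with per-segment `weights`, the `segments`
#'   raster, the weighted surrogate `r_squared`, and `constant_fn = TRUE`
#'   (all-zero weights) when the black box never changes its output.
#' @export
lime_explain <- function(predict_fn, image, target_class,
                         plan = superpixel_plan(), n_samples = 1000,
                         kernel_width = 0.25, ridge = 1, seed = 1) {
  segs <- make_superpixels(image, plan, seed = seed)
  M <- max(segs)
  if (n_samples < M + 2)
    stop_wbc("wbc_config_error", "n_samples must be >= n_segments + 2 (%d)", M + 2)
  base <- baseline_image(image, plan)
  Z <- with_seed(derive_seed(seed, "lime"),
                 matrix(as.integer(runif(n_samples * M) > 0.5), n_samples, M))
  Z[1, ] <- 1L
  probs <- predict_masked(predict_fn, image, base, segs, Z)
  y <- probs[, target_class + 1]
  if (max(y) - min(y) < 1e-12) {
    att <- new_attribution("lime", target_class, weights = numeric(M),
                           segments = segs,
                           extra = list(r_squared = NA_real_, constant_fn = TRUE))
    return(att)
  }
  dist <- 1 - sqrt(rowSums(Z) / M)          # cosine distance to all-ones
  w <- exp(-dist^2 / kernel_width^2)
  X <- cbind(1, Z)
  pen <- diag(c(0, rep(ridge, M)))
  beta <- solve(crossprod(X, X * w) + pen, crossprod(X, y * w))
  yhat <- as.vector(X %*% beta)
  ybar <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * (y - yhat)^2) / sum(w * (y - ybar)^2)
  new_attribution("lime", target_class, weights = as.vector(beta[-1]),
                  segments = segs,
                  extra = list(intercept = beta[1], r_squared = r2,
                               constant_fn = FALSE))
}

shapley_kernel_weight <- function(M, s) {
  (M - 1) / (choose(M, s) * s * (M - s))
}

#' Kernel SHAP over superpixels
#'
#' Shapley values of the segments for the target-class probability, by
#' weighted least squares with the Shapley kernel
#' `pi(z) = (M-1) / (choose(M,|z|) |z| (M-|z|))` under the efficiency
#' constraint `sum(phi) = f(full) - f(baseline)` (enforced exactly by
#' eliminating one coefficient). With `n_segments <= 12` all `2^M` subsets
#' are enumerated and the result is the exact Shapley value; otherwise
#' subsets are sampled from the kernel distribution.
#'
#' @inheritParams lime_explain
#' @param n_samples subset draws in sampled mode.
#' @return a `wbc_attribution` with per-segment Shapley values in
#'   `weights`, plus `f_full`, `f_baseline` and the `mode` used.
#' @export
kernel_shap <- function(predict_fn, image, target_class,
                        plan = superpixel_plan(), n_samples = 2048, seed = 1) {
  segs <- make_superpixels(image, plan, seed = seed)
  M <- max(segs)
  if (M < 2) stop_wbc("wbc_config_error", "kernel SHAP needs >= 2 segments")
  base <- baseline_image(image, plan)
  exact <- M <= 12
  if (exact) {
    Z <- as.matrix(expand.grid(rep(list(0:1), M)))
    colnames(Z) <- NULL
    sizes <- rowSums(Z)
    keep <- sizes > 0 & sizes < M
    Zr <- Z[keep, , drop = FALSE]
    w <- shapley_kernel_weight(M, sizes[keep])
  } else {
    sdist <- shapley_kernel_weight(M, 1:(M - 1)) * choose(M, 1:(M - 1))
    Zr <- with_seed(derive_seed(seed, "kshap"), {
      s <- sample(1:(M - 1), n_samples, replace = TRUE, prob = sdist / sum(sdist))
      t(vapply(s, function(si) {
        z <- integer(M); z[sample(M, si)] <- 1L; z
      }, integer(M)))
    })
    w <- rep(1, nrow(Zr))  # sampling follows the kernel, so weights are flat
  }
  ends <- matrix(c(rep(0L, M), rep(1L, M)), 2, M, byrow = TRUE)
  fe <- predict_masked(predict_fn, image, base, segs, ends)[, target_class + 1]
  f_base <- fe[1]; f_full <- fe[2]
  fz <- predict_masked(predict_fn, image, base, segs, Zr)[, target_class + 1]
  delta <- f_full - f_base
  # eliminate the last coefficient to enforce efficiency exactly
  yadj <- fz - f_base - Zr[, M] * delta
  Xadj <- Zr[, -M, drop = FALSE] - Zr[, M]
  XtW <- t(Xadj * w)
  phi_head <- solve(XtW %*% Xadj, XtW %*% yadj)
  phi <- c(as.vector(phi_head), delta - sum(phi_head))
  new_attribution("kshap", target_class, weights = phi, segments = segs,
                  extra = list(f_full = f_full, f_baseline = f_base,
                               mode = if (exact) "exact" else "sampled"))
}
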