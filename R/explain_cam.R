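# Gradient-based class activation maps. Definitions follow the original
# publications, restated here because they anchor the tests:
#
# Grad-CAM (Selvaraju et al.): for feature maps A^k of a conv layer and
# class score y_c (the pre-softmax logit), channel weights are the global
# average of the gradients, alpha_k = mean_ij d y_c / d A^k_ij, and the map
# is ReLU(sum_k alpha_k A^k), upsampled to the input and min-max normalized.
#
# Grad-CAM++ (Chattopadhay et al.): per-location weights
# alpha_ij^k = g_ij^2 / (2 g_ij^2 + sum_ab A_ab^k g_ij^3 + eps), g = d y_c /
# d A^k, channel weights w_k = sum_ij alpha_ij^k ReLU(g_ij), same map
# construction. For constant positive gradients this reduces to Grad-CAM's
# uniform average, and the stabilizer eps guards the 0/0 of dead units.

cam_finalize <- function(raw, input_hw) {
  raw[raw < 0] <- 0
  up <- if (all(dim(raw) == input_hw)) raw else {
    eb <- EBImage::Image(raw)
    EBImage::imageData(EBImage::resize(eb, w = input_hw[1], h = input_hw[2],
                                       filter = "bilinear"))
  }
  up[up < 0] <- 0
  mx <- max(up)
  if (mx > 0) up <- up / mx  # all-zero maps skip normalization by contract
  up
}

new_attribution <- function(method, target_class, map = NULL, weights = NULL,
                            segments = NULL, extra = list()) {
  structure(c(list(method = method, target_class = target_class, map = map,
                   weights = weights, segments = segments), extra),
            class = "wbc_attribution")
}

#' @export
print.wbc_attribution <- function(x, ...) {
  cat(sprintf("<wbc_attribution> method %s, class %d", x$method, x$target_class))
  if (!is.null(x$map)) cat(sprintf(", %dx%d map in [%.2f, %.2f]",
                                   nrow(x$map), ncol(x$map), min(x$map), max(x$map)))
  if (!is.null(x$weights)) cat(sprintf(", %d segment weights", length(x$weights)))
  cat("\n")
  invisible(x)
}

#' Grad-CAM saliency map
#'
#' Class-discriminative localization from the gradients of the class logit
#' with respect to a convolution block's feature maps.
#'
#' @param net a `wbc_network` or fitted `wbc_net`.
#' @param image `H x W x 3` input in `[0, 1]`.
#' @param target_class class id `0 .. n_classes-1`.
#' @param layer block name (`"block1"` ...); default the last conv block.
#' @return a `wbc_attribution` whose `map` is an `H x W` matrix in `[0, 1]`
#'   (all-zero when the class gradient vanishes everywhere).
#' @export
grad_cam <- function(net, image, target_class, layer = NULL) {
  if (inherits(net, "wbc_net")) net <- net$best
  sg <- saliency_gradient(net, image, target_class, layer)
  A <- sg$activation; dA <- sg$gradient
  alpha <- apply(dA, 3, mean)
  raw <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_along(alpha)) raw <- raw + alpha[k] * A[, , k]
  new_attribution("gradcam", target_class,
                  map = cam_finalize(raw, dim(image)[1:2]),
                  extra = list(layer = layer %||% names(net$taps)[length(net$taps)]))
}

#' Grad-CAM++ saliency map
#'
#' Sharper localization than Grad-CAM via per-location channel weights
#' built from powers of the class-score gradients.
#'
#' @inheritParams grad_cam
#' @param eps stabilizer added to the weight denominator.
#' @return a `wbc_attribution`; see [grad_cam()].
#' @export
grad_cam_pp <- function(net, image, target_class, layer = NULL, eps = 1e-8) {
  if (inherits(net, "wbc_net")) net <- net$best
  sg <- saliency_gradient(net, image, target_class, layer)
  A <- sg$activation; g <- sg$gradient
  K <- dim(A)[3]
  raw <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_len(K)) {
    gk <- g[, , k]
    sumA <- sum(A[, , k])
    denom <- 2 * gk^2 + sumA * gk^3
    alpha <- ifelse(abs(denom) > eps, gk^2 / denom, 0)
    wk <- sum(alpha * pmax(gk, 0))
    raw <- raw + wk * A[, , k]
  }
  new_attribution("gradcampp", target_class,
                  map = cam_finalize(raw, dim(image)[1:2]),
                  extra = list(layer = layer %||% names(net$taps)[length(net$taps)]))
}
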