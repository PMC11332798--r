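#' Jet-style colormap
#'
#' @param v numeric values in `[0, 1]`.
#' @return matrix with columns r, g, b in `[0, 1]`.
#' @export
jet_colors <- function(v) {
  cl <- function(x) pmin(pmax(x, 0), 1)
  cbind(r = cl(1.5 - abs(4 * v - 3)),
        g = cl(1.5 - abs(4 * v - 2)),
        b = cl(1.5 - abs(4 * v - 1)))
}

segment_boundaries <- function(segs) {
  H <- nrow(segs); W <- ncol(segs)
  b <- matrix(FALSE, H, W)
  b[-H, ] <- b[-H, ] | segs[-H, ] != segs[-1, ]
  b[-1, ] <- b[-1, ] | segs[-1, ] != segs[-H, ]
  b[, -W] <- b[, -W] | segs[, -W] != segs[, -1]
  b[, -1] <- b[, -1] | segs[, -1] != segs[, -W]
  b
}

#' Render an attribution over its image
#'
#' For CAM attributions, alpha-blends a jet colormap with per-pixel opacity
#' `alpha * map` (a zero map therefore returns the image unchanged). For
#' LIME, traces the boundaries of the `top_k` most positive segments in
#' yellow. For SHAP, tints segments by signed value: warm pink for positive
#' contributions, blue for negative. Pure visualization; no data mutation.
#'
#' @param image `H x W x 3` array (either `[0, 1]` or `[0, 255]` scale; the
#'   output keeps the input scale).
#' @param attribution a `wbc_attribution`.
#' @param alpha maximum blend opacity.
#' @param top_k segments outlined for LIME overlays.
#' @return image array of the same dimensions and scale.
#' @export
render_overlay <- function(image, attribution, alpha = 0.4, top_k = 5) {
  assert_image(image)
  scale <- if (max(image) > 1) 255 else 1
  img <- image / scale
  d <- dim(img)
  out <- img
  if (attribution$method %in% c("gradcam", "gradcampp")) {
    map <- attribution$map
    if (!all(dim(map) == d[1:2]))
      stop_wbc("wbc_shape_error", "attribution map does not match image size")
    cols <- jet_colors(as.vector(map))
    w <- alpha * as.vector(map)
    for (ch in 1:3)
      out[, , ch] <- (1 - w) * as.vector(img[, , ch]) + w * cols[, ch]
  } else if (attribution$method == "lime") {
    segs <- attribution$segments
    if (!all(dim(segs) == d[1:2]))
      stop_wbc("wbc_shape_error", "segment raster does not match image size")
    pos <- order(attribution$weights, decreasing = TRUE)
    pos <- pos[attribution$weights[pos] > 0]
    pos <- utils::head(pos, top_k)
    bnd <- segment_boundaries(segs) & (segs %in% pos)
    dim(bnd) <- dim(segs)
    yellow <- c(1, 1, 0)
    for (ch in 1:3) {
      pl <- out[, , ch]
      pl[bnd] <- yellow[ch]
      out[, , ch] <- pl
    }
  } else if (attribution$method == "kshap") {
    segs <- attribution$segments
    phi <- attribution$weights
    mx <- max(abs(phi))
    if (mx > 0) {
      rel <- phi[segs] / mx  # signed strength per pixel
      wpix <- alpha * abs(rel)
      warm <- c(1, 0.1, 0.6); cool <- c(0.1, 0.4, 1)  # pink / blue
      for (ch in 1:3) {
        tint <- ifelse(rel >= 0, warm[ch], cool[ch])
        out[, , ch] <- (1 - wpix) * as.vector(out[, , ch]) + wpix * tint
      }
    }
  } else {
    stop_wbc("wbc_config_error", "unknown attribution method %s",
             attribution$method)
  }
  out * scale
}
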