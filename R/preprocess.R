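#' Color band for nucleus thresholding
#'
#' The stained-nucleus segmentation keeps pixels whose three channels all lie
#' inside a fixed lower/upper bound pair. Defaults are the bounds used by the
#' extraction chain, `(80, 80, 180)`-`(180, 170, 245)`, expressed in the
#' loader channel order configured by
#' [pipeline_config()]`$channel_order_assumption`.
#'
#' @param lower,upper length-3 integer vectors, componentwise `lower <= upper`.
#' @return an object of class `wbc_color_range`.
#' @export
color_range <- function(lower = c(80, 80, 180), upper = c(180, 170, 245)) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 3 || length(upper) != 3)
    stop_wbc("wbc_config_error", "color bounds must be length-3 vectors")
  if (any(lower > upper))
    stop_wbc("wbc_config_error", "color range requires lower <= upper componentwise")
  structure(list(lower = lower, upper = upper), class = "wbc_color_range")
}

#' Resolve configured threshold bounds into loaded-RGB channel order
#'
#' Under the default `"swapped-BGR"` assumption the configured bounds are
#' read as blue/green/red triples (the common image-library convention), so
#' they are reversed before being compared with RGB-ordered pixels.
#'
#' @param range a [color_range()].
#' @param channel_order `"swapped-BGR"` or `"as-loaded-RGB"`.
#' @return a [color_range()] in RGB order.
#' @export
effective_range <- function(range, channel_order = c("swapped-BGR", "as-loaded-RGB")) {
  channel_order <- match.arg(channel_order)
  if (channel_order == "swapped-BGR")
    color_range(rev(range$lower), rev(range$upper))
  else range
}

#' Configuration of the cell-extraction chain
#'
#' Bundles every knob of the seven-step chain: pad, color-band threshold,
#' erode, dilate, contour selection, contour masking, crop and resize.
#'
#' @param pad_pixels border width added on all four sides (default 10).
#' @param pad_color RGB triple of the constant border; white by default so
#'   padding can never fall inside the threshold band.
#' @param channel_order_assumption how the printed threshold bounds relate to
#'   the loaded RGB channels: `"swapped-BGR"` (default; bounds are in BGR
#'   order, so the third printed component is red) or `"as-loaded-RGB"`.
#' @param color_range a [color_range()] with the threshold bounds.
#' @param struct_shape,struct_size structuring element for the morphology
#'   steps: `"ellipse"` (default; a 3x3 ellipse is the 4-neighbour cross) or
#'   `"square"`, with odd size `>= 3`.
#' @param erode_iters,dilate_iters iteration counts for erosion and dilation.
#' @param target_size side of the square output crop (default 120).
#' @param margin pixels added around the selected contour's bounding box
#'   before cropping, so the whole cell (not just the nucleus) is retained.
#' @param fallback what to do when thresholding finds nothing:
#'   `"center-crop"` returns the padded image's central square with
#'   `status = "fallback_used"`; `"reject"` raises a labeled error.
#' @return an object of class `wbc_pipeline_config`.
#' @export
pipeline_config <- function(pad_pixels = 10,
                            pad_color = c(255, 255, 255),
                            channel_order_assumption = c("swapped-BGR", "as-loaded-RGB"),
                            color_range = wbcnet::color_range(),
                            struct_shape = c("ellipse", "square"),
                            struct_size = 3,
                            erode_iters = 2,
                            dilate_iters = 2,
                            target_size = 120,
                            margin = 5,
                            fallback = c("center-crop", "reject")) {
  channel_order_assumption <- match.arg(channel_order_assumption)
  struct_shape <- match.arg(struct_shape)
  fallback <- match.arg(fallback)
  if (pad_pixels < 0) stop_wbc("wbc_config_error", "pad_pixels must be >= 0")
  if (target_size <= 0) stop_wbc("wbc_config_error", "target_size must be > 0")
  if (struct_size < 3 || struct_size %% 2 == 0)
    stop_wbc("wbc_config_error", "struct_size must be odd and >= 3")
  structure(list(pad_pixels = pad_pixels, pad_color = as.numeric(pad_color),
                 channel_order_assumption = channel_order_assumption,
                 color_range = color_range,
                 struct_shape = struct_shape, struct_size = struct_size,
                 erode_iters = erode_iters, dilate_iters = dilate_iters,
                 target_size = target_size, margin = margin, fallback = fallback),
            class = "wbc_pipeline_config")
}

#' Pad an image with a constant-color border
#'
#' @param img `H x W x 3` array.
#' @param p border width in pixels on each side.
#' @param color RGB triple of the border.
#' @return `(H+2p) x (W+2p) x 3` array.
#' @export
pad_image <- function(img, p = 10, color = c(255, 255, 255)) {
  assert_image(img)
  if (p < 0) stop_wbc("wbc_config_error", "padding size must be >= 0")
  if (p == 0) return(img)
  d <- dim(img)
  out <- array(rep(as.numeric(color), each = (d[1] + 2 * p) * (d[2] + 2 * p)),
               c(d[1] + 2 * p, d[2] + 2 * p, 3))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), ] <- img
  out
}

#' Spatial output size of a convolution
#'
#' `floor((n + 2p - f) / s) + 1` for input size `n`, padding `p`, filter
#' size `f` and stride `s`; used to validate network architectures before
#' any weights are allocated.
#'
#' @param n,p,f,s input size, padding, filter size, stride.
#' @return integer output size.
#' @export
conv_output_size <- function(n, p, f, s = 1) {
  if (s < 1) stop_wbc("wbc_config_error", "stride must be >= 1")
  if (f > n + 2 * p)
    stop_wbc("wbc_config_error",
             "filter size %d exceeds padded input %d", f, n + 2 * p)
  as.integer(floor((n + 2 * p - f) / s) + 1)
}

#' Binarize an image by componentwise color-band membership
#'
#' A pixel is foreground iff every channel lies within the corresponding
#' `[lower, upper]` bound of `range`.
#'
#' @param img `H x W x 3` array (same channel order as `range`).
#' @param range a [color_range()].
#' @return integer `H x W` matrix of 0/1.
#' @export
threshold_color <- function(img, range = color_range()) {
  assert_image(img)
  d <- dim(img)
  ch <- function(k) matrix(img[, , k], d[1], d[2])
  m <- (ch(1) >= range$lower[1] & ch(1) <= range$upper[1]) &
       (ch(2) >= range$lower[2] & ch(2) <= range$upper[2]) &
       (ch(3) >= range$lower[3] & ch(3) <= range$upper[3])
  matrix(as.integer(m), d[1], d[2])
}

#' Structuring element for binary morphology
#'
#' @param shape `"square"` (all ones) or `"ellipse"` (discrete ellipse; at
#'   size 3 this is the 4-neighbour cross).
#' @param size odd side length `>= 3`.
#' @return 0/1 matrix of dimension `size x size`.
#' @export
struct_element <- function(shape = c("ellipse", "square"), size = 3) {
  shape <- match.arg(shape)
  if (size < 3 || size %% 2 == 0)
    stop_wbc("wbc_config_error", "structuring element size must be odd and >= 3")
  if (shape == "square") return(matrix(1L, size, size))
  r <- (size - 1) / 2
  d <- outer((-r:r) / r, (-r:r) / r, function(a, b) a^2 + b^2)
  matrix(as.integer(d <= 1 + 1e-9), size, size)
}

# shared core: sliding min (erode) / max (dilate) over the element's support.
# Border convention: erosion treats out-of-image as foreground and dilation as
# background, which keeps erosion from eating the frame and makes the
# erosion/dilation duality on finite rasters exact.
morph_once <- function(mask, se, op) {
  r <- (nrow(se) - 1) / 2
  h <- nrow(mask); w <- ncol(mask)
  fillv <- if (op == "min") 1L else 0L
  padded <- matrix(fillv, h + 2 * r, w + 2 * r)
  padded[(r + 1):(r + h), (r + 1):(r + w)] <- mask
  acc <- NULL
  for (dj in -r:r) for (di in -r:r) {
    if (se[di + r + 1, dj + r + 1] == 0) next
    sub <- padded[(1 + r + di):(h + r + di), (1 + r + dj):(w + r + dj)]
    acc <- if (is.null(acc)) sub
           else if (op == "min") pmin(acc, sub) else pmax(acc, sub)
  }
  matrix(as.integer(acc), h, w)
}

#' Binary erosion
#'
#' Output pixel is 1 iff the structuring element translated there fits
#' entirely inside the foreground (out-of-image counts as foreground).
#'
#' @param mask 0/1 matrix.
#' @param se structuring element from [struct_element()].
#' @param iters number of erosion passes (`>= 1`).
#' @return eroded 0/1 matrix.
#' @export
erode <- function(mask, se = struct_element(), iters = 1) {
  if (iters < 1) stop_wbc("wbc_config_error", "iters must be >= 1")
  for (i in seq_len(iters)) mask <- morph_once(mask, se, "min")
  mask
}

#' Binary dilation
#'
#' Output pixel is 1 iff the reflected structuring element translated there
#' hits the foreground (out-of-image counts as background).
#'
#' @inheritParams erode
#' @return dilated 0/1 matrix.
#' @export
dilate <- function(mask, se = struct_element(), iters = 1) {
  if (iters < 1) stop_wbc("wbc_config_error", "iters must be >= 1")
  for (i in seq_len(iters)) mask <- morph_once(mask, se, "max")
  mask
}

#' Boundary of the largest connected foreground component
#'
#' Components use 8-connectivity; the largest-area component wins, with ties
#' broken by the smallest `(row0, col0)` of the bounding box. An empty mask
#' is a status, not an error.
#'
#' @param mask 0/1 matrix.
#' @return list with `contour` (n x 2 matrix of 1-based (row, col) boundary
#'   points, ordered), `bbox` (0-based half-open `c(row0, col0, row1, col1)`),
#'   `component` (0/1 matrix of the winning component), `filled` (component
#'   with interior holes filled) and `status` (`"ok"` or `"empty"`).
#' @export
find_main_contour <- function(mask) {
  if (!any(mask == 1))
    return(list(contour = matrix(numeric(0), 0, 2), bbox = NULL,
                component = mask * 0L, filled = mask * 0L, status = "empty"))
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0])
  best <- which(areas == max(areas))
  if (length(best) > 1) {
    # deterministic tie-break: lexicographically smallest bbox corner
    corner <- t(vapply(best, function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      c(min(idx[, 1]), min(idx[, 2]))
    }, numeric(2)))
    best <- best[order(corner[, 1], corner[, 2])][1]
  }
  comp <- matrix(as.integer(lab == best), nrow(mask), ncol(mask))
  filled <- matrix(as.integer(EBImage::fillHull(comp) > 0), nrow(mask), ncol(mask))
  oc <- EBImage::ocontour(comp)[[1]] + 1  # 0-based (row, col) -> 1-based
  idx <- which(comp == 1, arr.ind = TRUE)
  bbox <- c(min(idx[, 1]) - 1, min(idx[, 2]) - 1, max(idx[, 1]), max(idx[, 2]))
  list(contour = oc, bbox = bbox, component = comp, filled = filled, status = "ok")
}

#' Zero out an image outside a binary mask
#'
#' `R(x, y) = I(x, y) * M(x, y)` per channel.
#'
#' @param img `H x W x 3` array.
#' @param mask 0/1 matrix of the same spatial size.
#' @return masked image.
#' @export
apply_mask <- function(img, mask) {
  assert_image(img)
  if (!all(dim(img)[1:2] == dim(mask)))
    stop_wbc("wbc_shape_error", "image (%dx%d) and mask (%dx%d) differ in size",
             dim(img)[1], dim(img)[2], nrow(mask), ncol(mask))
  img * array(rep(as.numeric(mask), 3), dim(img))
}

#' Crop a bounding box and rescale to a square target
#'
#' Bilinear interpolation; when the crop already has the target size it is
#' returned unchanged.
#'
#' @param img `H x W x 3` array.
#' @param bbox 0-based half-open `c(row0, col0, row1, col1)` inside the image.
#' @param target output side length in pixels.
#' @return `target x target x 3` array.
#' @export
crop_and_resize <- function(img, bbox, target = 120) {
  assert_image(img)
  if (is.null(bbox) || length(bbox) != 4 || bbox[3] <= bbox[1] || bbox[4] <= bbox[2])
    stop_wbc("wbc_bbox_error", "empty or malformed bounding box")
  d <- dim(img)
  if (bbox[1] < 0 || bbox[2] < 0 || bbox[3] > d[1] || bbox[4] > d[2])
    stop_wbc("wbc_bbox_error", "bounding box outside image bounds")
  crop <- img[(bbox[1] + 1):bbox[3], (bbox[2] + 1):bbox[4], , drop = FALSE]
  if (dim(crop)[1] == target && dim(crop)[2] == target) return(crop)
  eb <- EBImage::Image(crop / 255, colormode = "Color")
  out <- EBImage::imageData(EBImage::resize(eb, w = target, h = target,
                                            filter = "bilinear"))
  array(out, c(target, target, 3)) * 255
}

#' Run the full cell-extraction chain on one image
#'
#' Executes pad, color-band threshold, erode, dilate, contour selection,
#' contour masking (the filled contour), and crop/resize, in that order.
#' When no pixel falls inside the threshold band the configured fallback is
#' applied: a central square crop (`status = "fallback_used"`) or rejection.
#'
#' @param img `H x W x 3` array in `[0, 255]`, RGB as loaded.
#' @param cfg a [pipeline_config()].
#' @param id optional provenance id carried into error messages.
#' @return an object of class `wbc_segmentation`: list with `cell_image`
#'   (`target x target x 3`), `mask` (post-morphology, padded coordinates),
#'   `contour`, `bbox` (crop box, 0-based half-open, padded coordinates) and
#'   `status` (`"ok"` or `"fallback_used"`).
#' @export
run_pipeline <- function(img, cfg = pipeline_config(), id = NULL) {
  assert_image(img)
  padded <- pad_image(img, cfg$pad_pixels, cfg$pad_color)
  band <- effective_range(cfg$color_range, cfg$channel_order_assumption)
  mask <- threshold_color(padded, band)
  se <- struct_element(cfg$struct_shape, cfg$struct_size)
  if (any(mask == 1)) {
    mask <- erode(mask, se, cfg$erode_iters)
    if (any(mask == 1)) mask <- dilate(mask, se, cfg$dilate_iters)
  }
  ct <- find_main_contour(mask)
  d <- dim(padded)
  if (ct$status == "empty") {
    if (cfg$fallback == "reject")
      stop_wbc("wbc_empty_contour",
               "no cell found%s: nothing inside the threshold band",
               if (is.null(id)) "" else paste0(" in ", id))
    side <- min(d[1], d[2])
    r0 <- floor((d[1] - side) / 2); c0 <- floor((d[2] - side) / 2)
    bbox <- c(r0, c0, r0 + side, c0 + side)
    cell <- crop_and_resize(padded, bbox, cfg$target_size)
    return(structure(list(cell_image = cell, mask = mask,
                          contour = ct$contour, bbox = bbox,
                          status = "fallback_used"),
                     class = "wbc_segmentation"))
  }
  masked <- apply_mask(padded, ct$filled)
  bbox <- c(max(ct$bbox[1] - cfg$margin, 0), max(ct$bbox[2] - cfg$margin, 0),
            min(ct$bbox[3] + cfg$margin, d[1]), min(ct$bbox[4] + cfg$margin, d[2]))
  cell <- crop_and_resize(masked, bbox, cfg$target_size)
  structure(list(cell_image = cell, mask = mask, contour = ct$contour,
                 bbox = bbox, status = "ok"),
            class = "wbc_segmentation")
}

#' @export
print.wbc_segmentation <- function(x, ...) {
  cat("<wbc_segmentation> status:", x$status,
      " crop:", paste(dim(x$cell_image)[1:2], collapse = "x"),
      if (!is.null(x$bbox)) paste0(" bbox: [", paste(x$bbox, collapse = ", "), ")"),
      "\n")
  invisible(x)
}

#' Intersection-over-union of two half-open bounding boxes
#'
#' @param a,b boxes `c(row0, col0, row1, col1)`, 0-based half-open.
#' @return IoU in `[0, 1]`.
#' @export
bbox_iou <- function(a, b) {
  ih <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iw <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ih * iw
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (union <= 0) return(0)
  inter / union
}
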