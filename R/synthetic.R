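#' Specification of a synthetic blood-smear image
#'
#' The generator emulates the properties the extraction chain relies on: a
#' pale background, distractor red-cell disks, and one dominant stained
#' nucleus whose color lies strictly inside the threshold band (by a safety
#' margin, so Gaussian pixel noise cannot push it outside) while background
#' and red cells lie outside the band. Class geometry follows the four
#' leukocyte morphologies: bilobed (eosinophil), one large round nucleus
#' filling most of the cell (lymphocyte), kidney-shaped (monocyte), and two
#' to five lobes joined by thin chromatin bridges (neutrophil).
#'
#' @param image_size square canvas side in pixels before the pipeline runs.
#' @param background_color,rbc_color RGB triples; both must fall outside the
#'   threshold band.
#' @param n_rbc_distractors number of red-cell disks composited first.
#' @param nucleus_color_range list of `lower`/`upper` RGB triples from which
#'   the single nucleus color is drawn; must lie strictly inside the band.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise,
#'   in 8-bit intensity units.
#' @param seed integer seed; every draw under this spec is deterministic.
#' @param threshold_range,channel_order the band the nucleus must sit in;
#'   defaults mirror [pipeline_config()].
#' @return an object of class `wbc_smear_spec`.
#' @export
smear_spec <- function(image_size = 240,
                       background_color = c(235, 225, 235),
                       rbc_color = c(240, 180, 175),
                       n_rbc_distractors = 12,
                       nucleus_color_range = list(lower = c(190, 90, 90),
                                                  upper = c(235, 160, 170)),
                       noise_sd = 4,
                       seed = 1,
                       threshold_range = color_range(),
                       channel_order = "swapped-BGR") {
  band <- effective_range(threshold_range, channel_order)
  inside <- function(x) all(x >= band$lower) && all(x <= band$upper)
  if (!inside(nucleus_color_range$lower) || !inside(nucleus_color_range$upper))
    stop_wbc("wbc_config_error",
             "nucleus_color_range must lie inside the threshold band %s-%s",
             paste(band$lower, collapse = ","), paste(band$upper, collapse = ","))
  if (inside(background_color))
    stop_wbc("wbc_config_error", "background_color must lie outside the threshold band")
  if (inside(rbc_color))
    stop_wbc("wbc_config_error", "rbc_color must lie outside the threshold band")
  structure(list(image_size = image_size, background_color = background_color,
                 rbc_color = rbc_color, n_rbc_distractors = n_rbc_distractors,
                 nucleus_color_range = nucleus_color_range, noise_sd = noise_sd,
                 seed = seed, band = band),
            class = "wbc_smear_spec")
}

disk_mask <- function(size, cy, cx, r) {
  g <- seq_len(size)
  outer((g - cy)^2, (g - cx)^2, `+`) <= r^2
}

#' Draw a class-shaped nucleus mask
#'
#' Geometry per class id: 0 two overlapping disks (bilobed); 1 one large disk
#' covering at least 40 percent of the cell disk; 2 a disk minus an offset
#' disk (kidney shape); 3 two to five small disks joined by thin bridges.
#'
#' @param label class id in `{0, 1, 2, 3}` (eosinophil, lymphocyte, monocyte,
#'   neutrophil).
#' @param spec a [smear_spec()].
#' @param rng_state integer seed making the draw deterministic.
#' @return 0/1 matrix with attributes `lobe_count`, `centroid` (row, col),
#'   `cell_center` and `cell_radius`.
#' @export
draw_nucleus <- function(label, spec = smear_spec(), rng_state = spec$seed) {
  if (!label %in% 0:3)
    stop_wbc("wbc_label_error", "unknown class label %s (expected 0-3)", label)
  S <- spec$image_size
  with_seed(rng_state, {
    cy <- S / 2 + runif(1, -0.05, 0.05) * S
    cx <- S / 2 + runif(1, -0.05, 0.05) * S
    rc <- runif(1, 0.16, 0.20) * S  # cell radius
    mask <- matrix(FALSE, S, S)
    lobes <- 1L
    if (label == 0) {            # bilobed: two large, solidly overlapping disks
      ang <- runif(1, 0, pi)
      sep <- 0.38 * rc           # half center distance; waist stays thick enough
      r1 <- runif(1, 0.55, 0.62) * rc  # to survive the morphology steps
      for (s in c(-1, 1))
        mask <- mask | disk_mask(S, cy + s * sep * sin(ang), cx + s * sep * cos(ang), r1)
      lobes <- 2L
    } else if (label == 1) {     # large round nucleus fills most of the cell
      mask <- disk_mask(S, cy, cx, runif(1, 0.78, 0.88) * rc)
    } else if (label == 2) {     # kidney: disk minus an offset bite
      ang <- runif(1, 0, 2 * pi)
      body <- disk_mask(S, cy, cx, 0.78 * rc)
      bite <- disk_mask(S, cy + 0.75 * rc * sin(ang), cx + 0.75 * rc * cos(ang),
                        0.55 * rc)
      mask <- body & !bite
    } else {                     # 2-5 small lobes on a ring, thin bridges
      lobes <- sample(2:5, 1)
      ang0 <- runif(1, 0, 2 * pi)
      ring <- 0.58 * rc
      th <- ang0 + 2 * pi * (seq_len(lobes) - 1) / lobes
      ys <- cy + ring * sin(th); xs <- cx + ring * cos(th)
      for (i in seq_len(lobes))
        mask <- mask | disk_mask(S, ys[i], xs[i], runif(1, 0.30, 0.38) * rc)
      if (lobes > 1) for (i in seq_len(lobes - 1)) {
        n <- 24
        t <- seq(0, 1, length.out = n)
        for (k in seq_len(n))
          mask <- mask | disk_mask(S, ys[i] + t[k] * (ys[i + 1] - ys[i]),
                                   xs[i] + t[k] * (xs[i + 1] - xs[i]), 3.2)
      }
    }
    idx <- which(mask, arr.ind = TRUE)
    structure(matrix(as.integer(mask), S, S),
              lobe_count = lobes,
              centroid = c(mean(idx[, 1]), mean(idx[, 2])),
              cell_center = c(cy, cx), cell_radius = rc)
  })
}

#' Render one labeled synthetic smear with ground truth
#'
#' Composites the pale background, the red-cell distractor disks (drawn
#' first, so the nucleus is never occluded), and the nucleus in one uniform
#' color sampled inside `nucleus_color_range`; Gaussian pixel noise is added
#' and intensities clipped to `[0, 255]`.
#'
#' @param label class id in `{0, 1, 2, 3}`.
#' @param spec a [smear_spec()]; `spec$seed` fixes the draw.
#' @return list with `image` (`S x S x 3`, integers in 0-255) and `truth`
#'   (list: `label`, `nucleus_mask` — the exact rendered support —
#'   `nucleus_bbox` 0-based half-open, `nucleus_centroid`, `lobe_count`).
#' @export
render_smear <- function(label, spec = smear_spec()) {
  nucleus <- draw_nucleus(label, spec, rng_state = derive_seed(spec$seed, "nucleus"))
  S <- spec$image_size
  with_seed(derive_seed(spec$seed, "render"), {
    img <- array(rep(spec$background_color, each = S * S), c(S, S, 3))
    for (i in seq_len(spec$n_rbc_distractors)) {
      ry <- runif(1, 0.05, 0.95) * S; rx <- runif(1, 0.05, 0.95) * S
      rr <- runif(1, 0.05, 0.08) * S
      jit <- runif(3, -5, 5)
      dm <- disk_mask(S, ry, rx, rr)
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[dm] <- spec$rbc_color[ch] + jit[ch]
        img[, , ch] <- pl
      }
    }
    lo <- spec$nucleus_color_range$lower; up <- spec$nucleus_color_range$upper
    ncol_ <- round(lo + runif(3) * (up - lo))
    nm <- nucleus == 1
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[nm] <- ncol_[ch]
      img[, , ch] <- pl
    }
    if (spec$noise_sd > 0)
      img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim(img))
    img <- round(pmin(pmax(img, 0), 255))
    idx <- which(nm, arr.ind = TRUE)
    bbox <- c(min(idx[, 1]) - 1, min(idx[, 2]) - 1, max(idx[, 1]), max(idx[, 2]))
    list(image = img,
         truth = list(label = label, nucleus_mask = nucleus,
                      nucleus_bbox = bbox,
                      nucleus_centroid = attr(nucleus, "centroid"),
                      lobe_count = attr(nucleus, "lobe_count"),
                      nucleus_color = ncol_))
  })
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes PNG files into one subdirectory per class (EOSINOPHIL, LYMPHOCYTE,
#' MONOCYTE, NEUTROPHIL) and a `manifest.csv` with columns
#' `path`, `label`, `seed`. A single global seed drives a per-image
#' substream, so the same `(spec, seed)` reproduces the dataset byte for
#' byte.
#'
#' @param n_per_class images per class (`>= 1`).
#' @param spec a [smear_spec()].
#' @param out_dir output directory (created if needed).
#' @param seed master seed; defaults to `spec$seed`.
#' @return the manifest as a data frame, invisibly written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
generate_dataset <- function(n_per_class, spec = smear_spec(), out_dir,
                             seed = spec$seed) {
  if (n_per_class < 1)
    stop_wbc("wbc_config_error", "n_per_class must be >= 1")
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop_wbc("wbc_io_error", "cannot create output directory %s", out_dir)
  classes <- wbc_classes()
  rows <- vector("list", 4 * n_per_class)
  k <- 0
  for (lab in 0:3) {
    cls_dir <- file.path(out_dir, classes[lab + 1])
    dir.create(cls_dir, showWarnings = FALSE)
    for (i in seq_len(n_per_class)) {
      k <- k + 1
      img_seed <- derive_seed(seed, "image", lab * n_per_class + i)
      sp <- spec; sp$seed <- img_seed
      sm <- render_smear(lab, sp)
      path <- file.path(cls_dir, sprintf("%s_%04d.png", tolower(classes[lab + 1]), i))
      write_image(sm$image, path)
      rows[[k]] <- data.frame(path = path, label = lab, seed = img_seed)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Render and preprocess a synthetic cell dataset in memory
#'
#' Convenience used by the scaled training experiments: renders
#' `n_per_class` smears per class, runs the extraction chain on each, and
#' stacks the crops into a network-ready array.
#'
#' @param n_per_class images per class.
#' @param spec a [smear_spec()].
#' @param cfg a [pipeline_config()] (its `target_size` fixes the crop side).
#' @param seed master seed for the per-image substreams.
#' @return list with `x` (`target x target x 3 x N` array scaled to
#'   `[0, 1]`), `y` (integer labels 0-3), `truth` (list of per-image ground
#'   truths) and `seg` (list of segmentation results).
#' @export
synthetic_cell_dataset <- function(n_per_class, spec = smear_spec(),
                                   cfg = pipeline_config(), seed = spec$seed) {
  n <- 4 * n_per_class
  t_ <- cfg$target_size
  x <- array(0, c(t_, t_, 3, n))
  y <- integer(n)
  truth <- vector("list", n)
  seg <- vector("list", n)
  k <- 0
  for (lab in 0:3) for (i in seq_len(n_per_class)) {
    k <- k + 1
    sp <- spec
    sp$seed <- derive_seed(seed, "image", lab * n_per_class + i)
    sm <- render_smear(lab, sp)
    sg <- run_pipeline(sm$image, cfg)
    x[, , , k] <- sg$cell_image / 255
    y[k] <- lab
    truth[[k]] <- sm$truth
    seg[[k]] <- sg
  }
  list(x = x, y = y, truth = truth, seg = seg)
}
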