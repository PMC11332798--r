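test_that("padding adds a constant border of the requested width", {
  img <- array(runif(120 * 120 * 3, 0, 255), c(120, 120, 3))
  out <- pad_image(img, 10, c(255, 255, 255))
  expect_equal(dim(out), c(140, 140, 3))
  expect_equal(out[11:130, 11:130, ], img)
  expect_equal(out[1, 1, ], c(255, 255, 255))
  expect_equal(out[140, 140, ], c(255, 255, 255))
  expect_identical(pad_image(img, 0), img)
})

test_that("conv output size follows the floor arithmetic", {
  expect_equal(conv_output_size(120, 0, 3, 1), 118L)
  expect_equal(conv_output_size(120, 1, 3, 1), 120L)
  expect_equal(conv_output_size(120, 0, 2, 2), 60L)
  expect_equal(conv_output_size(15, 0, 2, 2), 7L)
  expect_error(conv_output_size(5, 0, 7, 1), class = "wbc_config_error")
})

test_that("color-band thresholding is componentwise membership", {
  rng <- color_range()  # (80,80,180)-(180,170,245)
  px <- function(p) array(rep(p, each = 1), c(1, 1, 3))
  expect_equal(threshold_color(px(c(100, 100, 200)), rng)[1, 1], 1L)
  expect_equal(threshold_color(px(c(255, 255, 255)), rng)[1, 1], 0L)
  expect_equal(threshold_color(px(c(80, 80, 180)), rng)[1, 1], 1L)  # boundary
  expect_true(all(threshold_color(array(0, c(5, 5, 3)), rng) == 0L))
  # brute-force per-pixel check on a random image
  set.seed(11)
  img <- array(sample(0:255, 20 * 20 * 3, replace = TRUE), c(20, 20, 3))
  got <- threshold_color(img, rng)
  for (i in 1:20) for (j in 1:20) {
    v <- img[i, j, ]
    expect_identical(got[i, j],
                     as.integer(all(v >= rng$lower & v <= rng$upper)))
  }
})

test_that("the swapped-BGR assumption reverses the printed bounds", {
  er <- effective_range(color_range(), "swapped-BGR")
  expect_equal(er$lower, c(180, 80, 80))
  expect_equal(er$upper, c(245, 170, 180))
  expect_equal(effective_range(color_range(), "as-loaded-RGB")$lower,
               c(80, 80, 180))
})

test_that("erosion and dilation match the naive sliding-min/max oracles", {
  ses <- list(struct_element("square", 3), struct_element("ellipse", 3))
  set.seed(5)
  for (rep in 1:25) {
    m <- matrix(rbinom(144, 1, runif(1, 0.2, 0.8)), 12, 12)
    for (se in ses) {
      expect_identical(erode(m, se), naive_erode(m, se))
      expect_identical(dilate(m, se), naive_dilate(m, se))
    }
  }
  # degenerate cases
  single <- matrix(0L, 7, 7); single[4, 4] <- 1L
  expect_true(all(erode(single, struct_element("square", 3)) == 0L))
  block <- dilate(single, struct_element("square", 3))
  expect_equal(sum(block), 9)
  expect_true(all(block[3:5, 3:5] == 1L))
  expect_true(all(dilate(matrix(0L, 6, 6), struct_element()) == 0L))
  solid <- matrix(1L, 9, 9)
  expect_identical(erode(solid, struct_element("square", 3)), solid)
})

test_that("morphology satisfies anti-extensivity, extensivity and duality", {
  set.seed(6)
  se <- struct_element("square", 3)
  ref <- se[3:1, 3:1]
  for (rep in 1:20) {
    m <- matrix(rbinom(144, 1, 0.5), 12, 12)
    er <- erode(m, se); di <- dilate(m, se)
    expect_true(all(er <= m))          # erode(m) subset of m
    expect_true(all(m <= di))          # m subset of dilate(m)
    expect_identical(er, 1L - dilate(1L - m, ref))  # duality, pixel-exact
  }
})

test_that("main-contour selection keeps the largest component", {
  m <- matrix(0L, 20, 20)
  m[3:7, 3:7] <- 1L      # area 25
  m[12:14, 12:14] <- 1L  # area 9
  ct <- find_main_contour(m)
  expect_equal(ct$status, "ok")
  expect_equal(sum(ct$component), 25)
  expect_equal(ct$bbox, c(2, 2, 7, 7))
  expect_gt(nrow(ct$contour), 0)
  # contour points lie on the selected component
  expect_true(all(m[ct$contour] == 1L))
  empty <- find_main_contour(matrix(0L, 5, 5))
  expect_equal(empty$status, "empty")
  expect_equal(nrow(empty$contour), 0)
})

test_that("contour filling closes interior holes for masking", {
  m <- matrix(0L, 15, 15)
  m[4:12, 4:12] <- 1L
  m[7:9, 7:9] <- 0L  # hole
  ct <- find_main_contour(m)
  expect_true(all(ct$filled[7:9, 7:9] == 1L))
})

test_that("masking multiplies per channel", {
  img <- array(runif(100 * 100 * 3, 0, 255), c(100, 100, 3))
  ones <- matrix(1L, 100, 100)
  zeros <- matrix(0L, 100, 100)
  expect_equal(apply_mask(img, ones), img)
  expect_true(all(apply_mask(img, zeros) == 0))
  checker <- matrix(as.integer((row(ones) + col(ones)) %% 2), 100, 100)
  got <- apply_mask(img, checker)
  expect_true(all(got[, , 1][checker == 0] == 0))
  expect_equal(got[, , 2][checker == 1], img[, , 2][checker == 1])
  expect_error(apply_mask(img, matrix(1L, 10, 10)), class = "wbc_shape_error")
})

test_that("crop and resize obey the target geometry", {
  img <- array(runif(140 * 140 * 3, 0, 255), c(140, 140, 3))
  out <- crop_and_resize(img, c(0, 0, 140, 140), 120)
  expect_equal(dim(out), c(120, 120, 3))
  # identity when the crop is already target-sized
  out2 <- crop_and_resize(img, c(5, 7, 125, 127), 120)
  expect_equal(out2, img[6:125, 8:127, ])
  # interpolating a constant stays constant
  solid <- array(rep(c(10, 200, 30), each = 50 * 70), c(50, 70, 3))
  rs <- crop_and_resize(solid, c(0, 0, 50, 70), 24)
  expect_equal(max(abs(sweep(rs, 3, c(10, 200, 30)))), 0, tolerance = 1e-9)
  expect_error(crop_and_resize(img, c(10, 10, 10, 40), 24),
               class = "wbc_bbox_error")
  expect_error(crop_and_resize(img, c(0, 0, 200, 200), 24),
               class = "wbc_bbox_error")
})

test_that("the full chain localizes the synthetic nucleus", {
  sp <- smear_spec(seed = 3)
  sm <- render_smear(1, sp)
  sg <- run_pipeline(sm$image)
  expect_s3_class(sg, "wbc_segmentation")
  expect_equal(sg$status, "ok")
  expect_equal(dim(sg$cell_image), c(120, 120, 3))
  expect_gte(bbox_iou(sg$bbox, sm$truth$nucleus_bbox + 10), 0.7)
})

test_that("an image with nothing in the band falls back or rejects", {
  white <- array(255, c(60, 60, 3))
  sg <- run_pipeline(white, pipeline_config(target_size = 32))
  expect_equal(sg$status, "fallback_used")
  expect_equal(dim(sg$cell_image), c(32, 32, 3))
  expect_error(run_pipeline(white, pipeline_config(fallback = "reject"),
                            id = "img007"),
               "img007", class = "wbc_empty_contour")
})

test_that("thresholding a masked image never adds foreground", {
  set.seed(8)
  rng <- color_range(c(40, 40, 40), c(200, 200, 200))
  for (rep in 1:5) {
    img <- array(sample(0:255, 30 * 30 * 3, replace = TRUE), c(30, 30, 3))
    m1 <- threshold_color(img, rng)
    m2 <- threshold_color(apply_mask(img, m1), rng)
    expect_true(all(m2 <= m1))
  }
})
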