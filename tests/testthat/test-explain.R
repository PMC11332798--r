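test_that("Grad-CAM matches the closed form on a mean-readout toy net", {
  net <- toy_mean_net(hw = 8, seed = 1)
  set.seed(3)
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  att <- grad_cam(net, img, 0)
  A <- array(wbcnet:::net_forward(net, img, upto = 2)$out, c(8, 8, 4))
  expected <- pmax(A[, , 1], 0)
  expected <- expected / max(expected)
  expect_equal(att$map, expected, tolerance = 1e-12)
  expect_true(all(att$map >= 0 & att$map <= 1))
  expect_equal(max(att$map), 1)
})

test_that("a zero-gradient class yields an all-zero map without rescaling", {
  net <- toy_mean_net(hw = 8, seed = 1)
  set.seed(3)
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  # class 3 reads no feature map at all: gradient vanishes everywhere
  att <- grad_cam(net, img, 3)
  expect_true(all(att$map == 0))
  attpp <- grad_cam_pp(net, img, 3)
  expect_true(all(is.finite(attpp$map)))
  expect_error(grad_cam(net, img, 0, layer = "nope"), class = "wbc_layer_error")
})

test_that("Grad-CAM++ reduces to Grad-CAM under constant gradients", {
  net <- toy_mean_net(hw = 8, seed = 2)
  set.seed(5)
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  m1 <- grad_cam(net, img, 0)$map
  m2 <- grad_cam_pp(net, img, 0)$map
  expect_equal(m1, m2, tolerance = 1e-9)
})

test_that("CAM maps are invariant to positive rescaling of the logit head", {
  net <- toy_mean_net(hw = 8, seed = 2)
  net2 <- net
  L <- length(net2$layers)
  net2$layers[[L]]$W <- net2$layers[[L]]$W * 7
  set.seed(6)
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  expect_equal(grad_cam(net, img, 0)$map, grad_cam(net2, img, 0)$map,
               tolerance = 1e-9)
})

test_that("maps upsample to the input size on pooled architectures", {
  net <- build_network(scaled_network_spec(32), seed = 3)
  set.seed(7)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  for (att in list(grad_cam(net, img, 1), grad_cam_pp(net, img, 1))) {
    expect_equal(dim(att$map), c(32, 32))
    expect_true(all(att$map >= 0 & att$map <= 1))
  }
  a1 <- grad_cam(net, img, 1, layer = "block1")
  expect_equal(dim(a1$map), c(32, 32))
})

test_that("superpixel plans cover every pixel exactly once", {
  set.seed(8)
  img <- array(runif(30 * 30 * 3), c(30, 30, 3))
  for (plan in list(superpixel_plan("grid", 16),
                    superpixel_plan("slic-like", 12))) {
    segs <- make_superpixels(img, plan, seed = 2)
    expect_equal(dim(segs), c(30, 30))
    expect_true(all(segs >= 1))
    expect_equal(sort(unique(as.vector(segs))), seq_len(max(segs)))
  }
  expect_error(superpixel_plan(n_segments = 1), class = "wbc_config_error")
})

test_that("LIME recovers a planted linear segment model", {
  set.seed(5)
  img <- array(runif(24 * 24 * 3), c(24, 24, 3))
  plan <- superpixel_plan("grid", n_segments = 9)
  segs <- make_superpixels(img, plan)
  M <- max(segs)
  base <- wbcnet:::baseline_image(img, plan)
  w_true <- c(0.35, -0.3, 0.25, -0.2, 0.3, -0.25, 0.2, -0.35, 0.15)[1:M]
  pf <- planted_linear_box(segs, base, w_true)
  att <- lime_explain(pf, img, 0, plan, n_samples = 400, seed = 2)
  expect_gte(att$r_squared, 0.99)
  expect_equal(sign(att$weights), sign(w_true))
  expect_gt(stats::cor(att$weights, w_true / 10), 0.999)
  # determinism and the identity perturbation
  att2 <- lime_explain(pf, img, 0, plan, n_samples = 400, seed = 2)
  expect_identical(att$weights, att2$weights)
  expect_error(lime_explain(pf, img, 0, plan, n_samples = M),
               class = "wbc_config_error")
  # constant black box: flagged all-zero explanation
  att0 <- lime_explain(function(b) matrix(0.25, dim(b)[4], 4), img, 0, plan,
                       n_samples = 40, seed = 1)
  expect_true(att0$constant_fn)
  expect_true(all(att0$weights == 0))
})

test_that("exact Kernel SHAP equals subset-enumeration Shapley", {
  set.seed(9)
  img <- array(runif(18 * 18 * 3), c(18, 18, 3))
  plan <- superpixel_plan("grid", n_segments = 6)
  segs <- make_superpixels(img, plan)
  M <- max(segs)
  base <- wbcnet:::baseline_image(img, plan)
  # additive value function
  w_add <- c(0.3, -0.2, 0.1, 0.05, -0.15, 0.25)[1:M]
  pf <- planted_linear_box(segs, base, w_add, scale = 5)
  att <- kernel_shap(pf, img, 0, plan, seed = 4)
  expect_equal(att$mode, "exact")
  expect_equal(att$weights, w_add / 5, tolerance = 1e-6)
  phi_enum <- enum_shapley(function(z) 0.5 + sum(w_add * z) / 5, M)
  expect_equal(att$weights, phi_enum, tolerance = 1e-6)
  # a non-additive value function: still exact Shapley
  pf2 <- function(batch) {
    p <- pf(batch)
    cbind(p[, 1]^2, 1 - p[, 1]^2, 0, 0)
  }
  att2 <- kernel_shap(pf2, img, 0, plan, seed = 4)
  phi_enum2 <- enum_shapley(function(z) (0.5 + sum(w_add * z) / 5)^2, M)
  expect_equal(att2$weights, phi_enum2, tolerance = 1e-6)
  # efficiency holds exactly in both modes
  expect_equal(sum(att2$weights), att2$f_full - att2$f_baseline,
               tolerance = 1e-10)
  plan15 <- superpixel_plan("grid", n_segments = 15)
  segs15 <- make_superpixels(img, plan15)
  w15 <- seq(-0.3, 0.3, length.out = max(segs15))
  pf15 <- planted_linear_box(segs15, wbcnet:::baseline_image(img, plan15), w15)
  att15 <- kernel_shap(pf15, img, 0, plan15, n_samples = 600, seed = 4)
  expect_equal(att15$mode, "sampled")
  expect_equal(sum(att15$weights), att15$f_full - att15$f_baseline,
               tolerance = 1e-10)
})

test_that("symmetric segments in a symmetric game get equal Shapley values", {
  set.seed(10)
  img <- array(runif(12 * 12 * 3), c(12, 12, 3))
  plan <- superpixel_plan("grid", n_segments = 4)
  segs <- make_superpixels(img, plan)
  M <- max(segs)
  base <- wbcnet:::baseline_image(img, plan)
  probe <- t(vapply(seq_len(M), function(s)
    which(segs == s, arr.ind = TRUE)[1, ], numeric(2)))
  pf <- function(batch) {  # value depends only on how many segments are on
    N <- dim(batch)[4]
    out <- matrix(0, N, 4)
    for (j in seq_len(N)) {
      z <- vapply(seq_len(M), function(s)
        any(abs(batch[probe[s, 1], probe[s, 2], , j] -
                base[probe[s, 1], probe[s, 2], ]) > 1e-12), logical(1))
      out[j, 1] <- 0.2 + 0.1 * sum(z)^1.5
    }
    out
  }
  att <- kernel_shap(pf, img, 0, plan, seed = 1)
  expect_lt(diff(range(att$weights)), 1e-8)
})

test_that("overlays respect the blending contracts", {
  set.seed(11)
  img <- array(runif(20 * 20 * 3), c(20, 20, 3))
  zero <- wbcnet:::new_attribution("gradcam", 0, map = matrix(0, 20, 20))
  expect_equal(render_overlay(img, zero), img)
  sat <- wbcnet:::new_attribution("gradcam", 0, map = matrix(1, 20, 20))
  out <- render_overlay(img, sat, alpha = 0.4)
  expect_equal(dim(out), dim(img))
  cols <- jet_colors(1)
  expect_equal(out[3, 3, ], as.vector(0.6 * img[3, 3, ] + 0.4 * cols),
               tolerance = 1e-12)
  # 0-255 images keep their scale
  img255 <- img * 255
  out255 <- render_overlay(img255, zero)
  expect_equal(out255, img255)
  bad <- wbcnet:::new_attribution("gradcam", 0, map = matrix(0, 5, 5))
  expect_error(render_overlay(img, bad), class = "wbc_shape_error")
  # LIME and SHAP overlays keep dimensions
  plan <- superpixel_plan("grid", 4)
  segs <- make_superpixels(img, plan)
  lim <- wbcnet:::new_attribution("lime", 0, weights = c(1, -1, 0.5, 0),
                                  segments = segs)
  expect_equal(dim(render_overlay(img, lim)), dim(img))
  shp <- wbcnet:::new_attribution("kshap", 0, weights = c(0.2, -0.1, 0, 0.4),
                                  segments = segs)
  expect_equal(dim(render_overlay(img, shp)), dim(img))
})
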