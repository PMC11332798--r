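test_that("softmax lands on the simplex with shift invariance", {
  expect_equal(softmax(c(0, 0, 0, 0)), rep(0.25, 4))
  s <- c(1.3, -0.2, 0.7, 2.1)
  expect_equal(softmax(s), softmax(s + 100))
  big <- softmax(c(1000, 0))
  expect_true(all(is.finite(big)))
  expect_equal(big[1], 1, tolerance = 1e-12)
  set.seed(2)
  m <- matrix(rnorm(40, sd = 50), 10, 4)
  p <- softmax(m)
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-6)
})

test_that("cross entropy matches its closed forms", {
  expect_equal(cross_entropy_loss(rep(0.25, 4), 2), -log(0.25))
  expect_equal(cross_entropy_loss(c(0, 0, 1, 0), 2), 0, tolerance = 1e-9)
  two <- rbind(c(0.7, 0.1, 0.1, 0.1), c(0.25, 0.25, 0.25, 0.25))
  expect_equal(cross_entropy_loss(two, c(0, 3)),
               mean(c(-log(0.7), -log(0.25))))
  expect_error(cross_entropy_loss(rep(0.25, 4), 4), class = "wbc_label_error")
  expect_error(cross_entropy_loss(c(0.5, 0.1, 0.1, 0.1), 0),
               class = "wbc_config_error")
})

test_that("Glorot uniform limits and samples respect the bound", {
  expect_equal(glorot_uniform_limit(100, 100), sqrt(6 / 200))
  expect_equal(glorot_uniform_limit(3, 3), 1)
  expect_error(glorot_uniform_limit(0, 0), class = "wbc_config_error")
  set.seed(1)
  draws <- wbcnet:::glorot_draw(1e5, 50, 50)
  b <- glorot_uniform_limit(50, 50)
  expect_lte(max(draws), b)
  expect_gte(min(draws), -b)
  # every layer of a built network respects its own bound
  net <- build_network(scaled_network_spec(32), seed = 4)
  for (l in net$layers) {
    if (l$type == "conv") {
      ff <- dim(l$W)[1]; Ci <- dim(l$W)[2]; Fo <- dim(l$W)[3]
      expect_lte(max(abs(l$W)), glorot_uniform_limit(ff * Ci, ff * Fo))
    }
    if (l$type == "dense")
      expect_lte(max(abs(l$W)), glorot_uniform_limit(nrow(l$W), ncol(l$W)))
  }
})

test_that("one Nadam step reproduces the hand-transcribed update", {
  # independent transcription: biased moments, bias correction, Nesterov mix
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-7; eta <- 1e-5
  g <- 1; t <- 1
  m <- b1 * 0 + (1 - b1) * g
  v <- b2 * 0 + (1 - b2) * g^2
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  theta_hand <- 0 - eta / (sqrt(vhat) + eps) * (b1 * mhat + (1 - b1) * g / (1 - b1^t))
  st <- nadam_init(0, training_params(learning_rate = eta, beta1 = b1,
                                      beta2 = b2, epsilon = eps))
  got <- nadam_step(0, 1, st)
  expect_equal(got$params, theta_hand, tolerance = 1e-12)
  # zero gradient on fresh state leaves parameters unchanged
  st0 <- nadam_init(5, training_params())
  expect_equal(nadam_step(5, 0, st0)$params, 5)
  expect_error(nadam_step(0, NaN, nadam_init(0)), class = "wbc_numeric_error")
})

test_that("Nadam descends a scalar quadratic monotonically", {
  st <- nadam_init(1, training_params(learning_rate = 1e-5))
  theta <- 1
  losses <- numeric(1000)
  for (i in 1:1000) {
    g <- 2 * theta  # d/dtheta theta^2
    up <- nadam_step(theta, g, st)
    theta <- up$params; st <- up$state
    losses[i] <- theta^2
  }
  expect_true(all(diff(losses) < 0))
})

test_that("build_network follows the declared six-block architecture", {
  net <- build_network(proposed_network_spec(), seed = 1)
  types <- vapply(net$layers, function(l) l$type, character(1))
  expect_equal(sum(types == "conv"), 2)       # block 1: two standard convs
  expect_equal(sum(types == "sepconv"), 10)   # blocks 2-6: two each
  expect_equal(sum(types == "bnorm"), 5)
  expect_equal(sum(types == "maxpool"), 6)
  expect_equal(names(net$taps), paste0("block", 1:6))
  # spatial walk 120 -> 60 -> 30 -> 15 -> 7 -> 3 -> 1 via the conv-output rule
  sz <- 120
  for (i in 1:6) sz <- conv_output_size(sz, 0, 2, 2)
  expect_equal(sz, 1L)
  # head: 512, 128, 64, then 4-way output
  dense <- Filter(function(l) l$type == "dense", net$layers)
  expect_equal(vapply(dense, function(l) ncol(l$W), numeric(1)),
               c(512, 128, 64, 4))
  drops <- vapply(Filter(function(l) l$type == "dropout", net$layers),
                  function(l) l$rate, numeric(1))
  expect_equal(drops, c(0.2, 0.2, 0.7, 0.5, 0.3))  # blocks 4-5, then head
})

test_that("parameter count matches an independent layer-by-layer sum", {
  net <- build_network(proposed_network_spec(), seed = 1)
  # closed form: standard conv 9*Cin*Cout + Cout; separable 9*Cin + Cin*Cout
  # + Cout; batchnorm 2C; dense nin*nout + nout
  filt <- c(16, 32, 64, 128, 256, 256)
  expected <- 0
  Cin <- 3
  for (b in 1:6) {
    nlay <- 2
    for (l in seq_len(nlay)) {
      if (b == 1) expected <- expected + 9 * Cin * filt[b] + filt[b]
      else expected <- expected + 9 * Cin + Cin * filt[b] + filt[b]
      Cin <- filt[b]
    }
    if (b > 1) expected <- expected + 2 * filt[b]
  }
  nin <- 1 * 1 * 256
  for (u in c(512, 128, 64)) {
    expected <- expected + nin * u + u
    nin <- u
  }
  expected <- expected + nin * 4 + 4
  expect_equal(n_params(net), expected)
})

test_that("network outputs are softmax-normalizable and reproducible", {
  spec <- scaled_network_spec(32)
  net <- build_network(spec, seed = 7)
  net2 <- build_network(spec, seed = 7)
  expect_identical(wbcnet:::collect_params(net), wbcnet:::collect_params(net2))
  net3 <- build_network(spec, seed = 8)
  expect_false(identical(wbcnet:::collect_params(net),
                         wbcnet:::collect_params(net3)))
  set.seed(1)
  x <- array(runif(32 * 32 * 3 * 5), c(32, 32, 3, 5))
  p <- network_predict(net, x)
  expect_equal(dim(p), c(5, 4))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  # architecture validation: pooling a too-small input must fail
  bad <- network_spec(input_shape = c(4, 4, 3),
                      blocks = list(block_spec(1, 4, "standard"),
                                    block_spec(1, 4, "separable"),
                                    block_spec(1, 4, "separable")),
                      head_units = 4, head_dropout = 0)
  expect_error(build_network(bad, seed = 1), class = "wbc_config_error")
})

test_that("backpropagation matches central finite differences", {
  spec <- network_spec(input_shape = c(8, 8, 3),
                       blocks = list(block_spec(1, 4, "standard",
                                                batch_norm = FALSE),
                                     block_spec(1, 4, "separable")),
                       head_units = 6, head_dropout = 0, n_classes = 4)
  net <- build_network(spec, seed = 2)
  set.seed(9)
  x <- array(runif(8 * 8 * 3 * 3), c(8, 8, 3, 3))
  y <- c(0, 2, 3)
  lossfun <- function(nt)
    wbcnet:::softmax_ce(wbcnet:::net_forward(nt, x, training = TRUE)$out, y)$loss
  fw <- wbcnet:::net_forward(net, x, training = TRUE, keep_caches = TRUE)
  sc <- wbcnet:::softmax_ce(fw$out, y)
  bw <- wbcnet:::net_backward(net, fw$caches, sc$dlogits)
  ga <- wbcnet:::collect_grads(net, bw$grads)
  h <- 1e-5
  set.seed(4)
  for (nm in names(ga)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    i <- as.integer(parts[1]); p <- parts[2]
    for (j in sample(length(ga[[nm]]), min(5, length(ga[[nm]])))) {
      ntp <- net; ntm <- net
      ntp$layers[[i]][[p]][j] <- ntp$layers[[i]][[p]][j] + h
      ntm$layers[[i]][[p]][j] <- ntm$layers[[i]][[p]][j] - h
      gn <- (lossfun(ntp) - lossfun(ntm)) / (2 * h)
      expect_lt(abs(gn - ga[[nm]][j]) / max(1e-8, abs(gn) + abs(ga[[nm]][j])),
                1e-3)
    }
  }
})
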