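#' Declarative description of one convolution block
#'
#' @param n_conv_layers number of convolution layers in the block.
#' @param filters output channels of every convolution in the block.
#' @param conv_kind `"standard"` or `"separable"` (depthwise then pointwise).
#' @param batch_norm add channelwise batch normalization after the
#'   activations.
#' @param pool end the block with 2x2 stride-2 max pooling.
#' @param dropout dropout rate applied after pooling, or `NA` for none.
#' @return an object of class `wbc_block_spec`.
#' @export
block_spec <- function(n_conv_layers, filters,
                       conv_kind = c("separable", "standard"),
                       batch_norm = TRUE, pool = TRUE, dropout = NA) {
  conv_kind <- match.arg(conv_kind)
  if (n_conv_layers < 1 || filters < 1)
    stop_wbc("wbc_config_error", "block needs >= 1 conv layers and >= 1 filters")
  if (!is.na(dropout) && (dropout < 0 || dropout >= 1))
    stop_wbc("wbc_config_error", "dropout rate must lie in [0, 1)")
  structure(list(n_conv_layers = n_conv_layers, filters = filters,
                 conv_kind = conv_kind, batch_norm = batch_norm,
                 pool = pool, dropout = dropout),
            class = "wbc_block_spec")
}

#' Declarative network architecture
#'
#' The proposed classifier (see [proposed_network_spec()]) has six blocks:
#' block 1 holds two standard convolutions of 16 filters without batch
#' normalization; blocks 2-6 use depthwise-separable convolutions with batch
#' normalization, and blocks 4 and 5 carry dropout 0.2. The dense head is
#' 512/128/64 units with hyperbolic-tangent activations and dropout rates
#' 0.7/0.5/0.3, followed by a 4-way softmax. Convolutions are 3x3, stride 1,
#' "same" zero padding; pooling is 2x2 stride 2 (so a 120-pixel input walks
#' 120-60-30-15-7-3-1 through six pools).
#'
#' @param input_shape `c(H, W, C)` of the network input.
#' @param blocks list of [block_spec()]s.
#' @param head_units,head_dropout dense head sizes and dropout rates
#'   (equal lengths).
#' @param head_activation activation of the dense head (`"tanh"` or
#'   `"relu"`).
#' @param conv_activation activation after each convolution.
#' @param n_classes number of output classes.
#' @param kernel_size odd convolution kernel side (default 3).
#' @return an object of class `wbc_network_spec`.
#' @export
network_spec <- function(input_shape = c(120, 120, 3),
                         blocks = default_blocks(),
                         head_units = c(512, 128, 64),
                         head_dropout = c(0.7, 0.5, 0.3),
                         head_activation = c("tanh", "relu"),
                         conv_activation = "relu",
                         n_classes = 4,
                         kernel_size = 3) {
  head_activation <- match.arg(head_activation)
  if (length(head_units) != length(head_dropout))
    stop_wbc("wbc_config_error", "head_units and head_dropout lengths differ")
  if (any(head_dropout < 0 | head_dropout >= 1))
    stop_wbc("wbc_config_error", "dropout rates must lie in [0, 1)")
  if (kernel_size %% 2 == 0) stop_wbc("wbc_config_error", "kernel_size must be odd")
  structure(list(input_shape = input_shape, blocks = blocks,
                 head_units = head_units, head_dropout = head_dropout,
                 head_activation = head_activation,
                 conv_activation = conv_activation,
                 n_classes = n_classes, kernel_size = kernel_size),
            class = "wbc_network_spec")
}

#' @rdname network_spec
#' @export
default_blocks <- function() {
  list(block_spec(2, 16, "standard", batch_norm = FALSE),
       block_spec(2, 32, "separable"),
       block_spec(2, 64, "separable"),
       block_spec(2, 128, "separable", dropout = 0.2),
       block_spec(2, 256, "separable", dropout = 0.2),
       block_spec(2, 256, "separable"))
}

#' @rdname network_spec
#' @export
proposed_network_spec <- function() network_spec()

#' A desk-scale variant of the architecture
#'
#' Three blocks and a small head for 48x48 crops: enough capacity to
#' separate the four synthetic nuclear morphologies in minutes on one CPU
#' while exercising every layer type of the full network.
#'
#' @param input_size square input side (default 48).
#' @return a [network_spec()].
#' @export
scaled_network_spec <- function(input_size = 48) {
  network_spec(input_shape = c(input_size, input_size, 3),
               blocks = list(block_spec(1, 8, "standard", batch_norm = FALSE),
                             block_spec(1, 16, "separable"),
                             block_spec(1, 32, "separable", dropout = 0.2)),
               head_units = 64, head_dropout = 0.2)
}

#' Support bound of the Glorot (Xavier) uniform initializer
#'
#' Weights are drawn from `U(-b, b)` with `b = sqrt(6 / (n_in + n_out))`.
#'
#' @param n_in,n_out fan-in and fan-out of the layer.
#' @return the bound `b`.
#' @export
glorot_uniform_limit <- function(n_in, n_out) {
  if (n_in + n_out <= 0 || n_in < 0 || n_out < 0)
    stop_wbc("wbc_config_error", "fan sizes must be nonnegative with positive sum")
  sqrt(6 / (n_in + n_out))
}

glorot_draw <- function(n, n_in, n_out) {
  b <- glorot_uniform_limit(n_in, n_out)
  runif(n, -b, b)
}

#' Build a network from its spec
#'
#' Allocates all layers with Glorot-uniform weights and zero biases; layout
#' per block is conv -> activation (per layer), then batch norm, max pool
#' and dropout, followed by flatten and the dense head. Every block's
#' feature map (the pooling input) is exposed by name (`"block1"`, ...,
#' `"block6"`) for the explanation methods.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed; the same seed reproduces identical weights.
#' @return an object of class `wbc_network`.
#' @export
build_network <- function(spec, seed = 1) {
  f <- spec$kernel_size
  r <- (f - 1) / 2
  h <- spec$input_shape[1]; w <- spec$input_shape[2]; C <- spec$input_shape[3]
  layers <- list()
  taps <- integer(0)
  with_seed(seed, {
    for (bi in seq_along(spec$blocks)) {
      blk <- spec$blocks[[bi]]
      for (li in seq_len(blk$n_conv_layers)) {
        # "same" padding keeps h, w; validate via the conv-output arithmetic
        ho <- conv_output_size(h, r, f, 1)
        if (ho <= 0)
          stop_wbc("wbc_config_error", "spatial size underflow in block %d", bi)
        Fo <- blk$filters
        if (blk$conv_kind == "standard") {
          W <- array(glorot_draw(f * f * C * Fo, f * f * C, f * f * Fo),
                     c(f * f, C, Fo))
          layers[[length(layers) + 1]] <-
            list(type = "conv", name = sprintf("block%d_conv%d", bi, li),
                 W = W, b = numeric(Fo), r = r)
        } else {
          D <- matrix(glorot_draw(f * f * C, f * f, f * f), f * f, C)
          P <- matrix(glorot_draw(C * Fo, C, Fo), C, Fo)
          layers[[length(layers) + 1]] <-
            list(type = "sepconv", name = sprintf("block%d_sepconv%d", bi, li),
                 D = D, P = P, b = numeric(Fo), r = r)
        }
        layers[[length(layers) + 1]] <- list(type = spec$conv_activation,
                                             name = sprintf("block%d_act%d", bi, li))
        C <- Fo
      }
      if (blk$batch_norm)
        layers[[length(layers) + 1]] <-
          list(type = "bnorm", name = sprintf("block%d_bn", bi),
               gamma = rep(1, C), beta = numeric(C),
               run_mean = numeric(C), run_var = rep(1, C),
               momentum = 0.9, eps = 1e-5)
      taps[sprintf("block%d", bi)] <- length(layers)
      if (blk$pool) {
        if (h < 2 || w < 2)
          stop_wbc("wbc_config_error", "spatial size underflow at pool of block %d", bi)
        layers[[length(layers) + 1]] <- list(type = "maxpool",
                                             name = sprintf("block%d_pool", bi))
        h <- h %/% 2; w <- w %/% 2
      }
      if (!is.na(blk$dropout))
        layers[[length(layers) + 1]] <- list(type = "dropout", rate = blk$dropout,
                                             name = sprintf("block%d_drop", bi))
    }
    layers[[length(layers) + 1]] <- list(type = "flatten", name = "flatten")
    nin <- h * w * C
    for (di in seq_along(spec$head_units)) {
      no <- spec$head_units[di]
      layers[[length(layers) + 1]] <-
        list(type = "dense", name = sprintf("dense%d", di),
             W = matrix(glorot_draw(nin * no, nin, no), nin, no), b = numeric(no))
      layers[[length(layers) + 1]] <- list(type = spec$head_activation,
                                           name = sprintf("dense%d_act", di))
      layers[[length(layers) + 1]] <- list(type = "dropout",
                                           rate = spec$head_dropout[di],
                                           name = sprintf("dense%d_drop", di))
      nin <- no
    }
    layers[[length(layers) + 1]] <-
      list(type = "dense", name = "logits",
           W = matrix(glorot_draw(nin * spec$n_classes, nin, spec$n_classes),
                      nin, spec$n_classes),
           b = numeric(spec$n_classes))
  })
  structure(list(spec = spec, layers = layers, taps = taps, seed = seed),
            class = "wbc_network")
}

#' @export
print.wbc_network <- function(x, ...) {
  cat(sprintf("<wbc_network> %d blocks, input %s, %d classes, %d parameters\n",
              length(x$spec$blocks),
              paste(x$spec$input_shape, collapse = "x"),
              x$spec$n_classes, n_params(x)))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param net a `wbc_network` or fitted `wbc_net`.
#' @return integer parameter count.
#' @export
n_params <- function(net) {
  if (inherits(net, "wbc_net")) net <- net$network
  sum(vapply(net$layers, function(l)
    sum(vapply(layer_param_names(l), function(p) length(l[[p]]), numeric(1)), 0),
    numeric(1)))
}

# forward through all layers (or up to `upto`); returns the final output,
# caches, batch-norm running-stat updates and the output spatial dims of
# every conv-trunk layer. Input arrays (H, W, C, N) are converted once into
# the internal spatial-major trunk layout.
net_forward <- function(net, x, training = FALSE, keep_caches = FALSE,
                        upto = NULL) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  d <- dim(x)
  sdim <- c(d[1], d[2], d[4])
  x <- aperm(x, c(1, 2, 4, 3))
  dim(x) <- c(d[1] * d[2] * d[4], d[3])
  caches <- if (keep_caches) vector("list", length(net$layers)) else NULL
  run_updates <- list()
  sdims <- vector("list", length(net$layers))
  last <- upto %||% length(net$layers)
  for (i in seq_len(last)) {
    fr <- layer_forward(net$layers[[i]], x, training, sdim)
    x <- fr$y
    if (!is.null(fr$cache) && keep_caches) caches[[i]] <- fr$cache
    if ("sdim" %in% names(fr)) sdim <- fr$sdim
    sdims[i] <- list(sdim)
    if (!is.null(fr$run_update)) run_updates[[as.character(i)]] <- fr$run_update
  }
  list(out = x, caches = caches, run_updates = run_updates, sdims = sdims)
}

# backward from dlogits; returns per-layer parameter gradients and, when
# `downto` is given, the gradient w.r.t. that layer's output
net_backward <- function(net, caches, dout, downto = 0) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_len(length(net$layers)))) {
    if (i <= downto) break
    br <- layer_backward(net$layers[[i]], caches[[i]], dout,
                         need_dx = (i > 1 || downto > 0))
    grads[i] <- list(br$grads)   # keep NULL slots for parameter-free layers
    dout <- br$dx
  }
  list(grads = grads, dx = dout)
}

apply_run_updates <- function(net, run_updates) {
  for (nm in names(run_updates)) {
    i <- as.integer(nm)
    l <- net$layers[[i]]
    mom <- l$momentum
    net$layers[[i]]$run_mean <- mom * l$run_mean + (1 - mom) * run_updates[[nm]]$mean
    net$layers[[i]]$run_var <- mom * l$run_var + (1 - mom) * run_updates[[nm]]$var
  }
  net
}

#' Class probabilities for a batch of inputs
#'
#' Runs the network in inference mode (running batch-norm statistics, no
#' dropout) and applies the softmax.
#'
#' @param net a `wbc_network`.
#' @param x `H x W x C x N` array (or a single `H x W x C` image) in `[0, 1]`.
#' @return `N x n_classes` matrix of probabilities.
#' @export
network_predict <- function(net, x) {
  softmax(net_forward(net, x, training = FALSE)$out)
}

# activation and d(logit_class)/d(activation) at a named conv block
saliency_gradient <- function(net, x, class_id, layer = NULL) {
  layer <- layer %||% names(net$taps)[length(net$taps)]
  if (!layer %in% names(net$taps))
    stop_wbc("wbc_layer_error", "unknown layer name %s (have: %s)", layer,
             paste(names(net$taps), collapse = ", "))
  ti <- net$taps[[layer]]
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  fw <- net_forward(net, x, training = FALSE, keep_caches = TRUE)
  K <- ncol(fw$out)
  if (class_id < 0 || class_id >= K)
    stop_wbc("wbc_label_error", "class id %s out of range 0-%d", class_id, K - 1)
  dout <- matrix(0, nrow(fw$out), K)
  dout[, class_id + 1] <- 1
  # re-run up to the tapped layer to recover its output activation
  af <- net_forward(net, x, training = FALSE, upto = ti)
  bw <- net_backward(net, fw$caches, dout, downto = ti)
  s <- fw$sdims[[ti]]  # (H, W, N) of the tapped feature map; here N = 1
  list(activation = array(af$out, c(s[1], s[2], ncol(af$out))),
       gradient = array(bw$dx, c(s[1], s[2], ncol(bw$dx))),
       logits = fw$out)
}
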