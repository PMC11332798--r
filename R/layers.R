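# Internal layer mechanics.
#
# Convolution-trunk activations travel as (H*W*N) x C matrices whose rows
# enumerate spatial position (fastest) then image, and whose columns are
# channels; `sdim = c(H, W, N)` rides alongside in the forward driver. In
# this layout a 3x3 convolution is nine row-gathers plus nine BLAS matrix
# products (one per kernel offset), batch normalization is plain column
# arithmetic, and no array permutation happens inside the hot loop. The
# dense head uses ordinary (N x features) matrices. Every layer implements
# forward -> (output, cache) and backward -> (input gradient, parameter
# gradients); backward replays from the cache only.

# row indices of every (position, image) pair inside the zero-padded
# (Hp*Wp*N) frame, one column per kernel offset; column 0 is the pad
# placement map itself. Memoized: batch shapes repeat every step.
.offset_cache <- new.env(parent = emptyenv())

offset_rows <- function(H, W, N, r) {
  key <- paste(H, W, N, r, sep = "x")
  hit <- .offset_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- offset_rows_build(H, W, N, r)
  if (length(ls(.offset_cache)) > 32) rm(list = ls(.offset_cache), envir = .offset_cache)
  .offset_cache[[key]] <- val
  val
}

offset_rows_build <- function(H, W, N, r) {
  f <- 2L * r + 1L
  Hp <- H + 2L * r; Wp <- W + 2L * r
  oi <- rep(seq_len(H), W)
  oj <- rep(seq_len(W), each = H)
  img <- (0:(N - 1)) * (Hp * Wp)
  out <- vector("list", f * f + 1L)
  out[[1]] <- as.vector(outer(oi + r + (oj + r - 1L) * Hp, img, `+`))
  k <- 1L
  for (dj in 0:(f - 1L)) for (di in 0:(f - 1L)) {  # di fastest: array order
    k <- k + 1L
    out[[k]] <- as.vector(outer(oi + di + (oj + dj - 1L) * Hp, img, `+`))
  }
  out
}

trunk_pad <- function(x, sdim, r) {
  Hp <- sdim[1] + 2L * r; Wp <- sdim[2] + 2L * r
  R <- offset_rows(sdim[1], sdim[2], sdim[3], r)
  Xp <- matrix(0, Hp * Wp * sdim[3], ncol(x))
  Xp[R[[1]], ] <- x
  list(Xp = Xp, R = R)
}

wslice <- function(W, k) matrix(W[k, , ], dim(W)[2], dim(W)[3])

fwd_conv <- function(layer, x, sdim) {
  ff <- dim(layer$W)[1]
  p <- trunk_pad(x, sdim, layer$r)
  out <- matrix(0, nrow(x), dim(layer$W)[3])
  for (k in seq_len(ff))
    out <- out + p$Xp[p$R[[k + 1]], , drop = FALSE] %*% wslice(layer$W, k)
  out <- out + rep(layer$b, each = nrow(out))
  list(y = out, cache = list(Xp = p$Xp, R = p$R, sdim = sdim), sdim = sdim)
}

bwd_conv <- function(layer, cache, dy, need_dx = TRUE) {
  ff <- dim(layer$W)[1]
  dW <- array(0, dim(layer$W))
  dXp <- if (need_dx) matrix(0, nrow(cache$Xp), ncol(cache$Xp)) else NULL
  for (k in seq_len(ff)) {
    rows <- cache$R[[k + 1]]
    dW[k, , ] <- crossprod(cache$Xp[rows, , drop = FALSE], dy)
    if (need_dx)
      dXp[rows, ] <- dXp[rows, , drop = FALSE] + tcrossprod(dy, wslice(layer$W, k))
  }
  list(dx = if (need_dx) dXp[cache$R[[1]], , drop = FALSE],
       grads = list(W = dW, b = colSums(dy)))
}

fwd_sepconv <- function(layer, x, sdim) {
  ff <- nrow(layer$D)
  p <- trunk_pad(x, sdim, layer$r)
  z <- matrix(0, nrow(x), ncol(x))
  for (k in seq_len(ff))
    z <- z + p$Xp[p$R[[k + 1]], , drop = FALSE] * rep(layer$D[k, ], each = nrow(x))
  out <- z %*% layer$P
  out <- out + rep(layer$b, each = nrow(out))
  list(y = out, cache = list(Xp = p$Xp, R = p$R, z = z, sdim = sdim), sdim = sdim)
}

bwd_sepconv <- function(layer, cache, dy, need_dx = TRUE) {
  ff <- nrow(layer$D)
  n <- nrow(dy)
  dP <- crossprod(cache$z, dy)
  dz <- tcrossprod(dy, layer$P)
  dD <- matrix(0, ff, ncol(layer$D))
  dXp <- if (need_dx) matrix(0, nrow(cache$Xp), ncol(cache$Xp)) else NULL
  for (k in seq_len(ff)) {
    rows <- cache$R[[k + 1]]
    Sk <- cache$Xp[rows, , drop = FALSE]
    dD[k, ] <- colSums(Sk * dz)
    if (need_dx)
      dXp[rows, ] <- dXp[rows, , drop = FALSE] + dz * rep(layer$D[k, ], each = n)
  }
  list(dx = if (need_dx) dXp[cache$R[[1]], , drop = FALSE],
       grads = list(D = dD, P = dP, b = colSums(dy)))
}

fwd_relu <- function(layer, x) {
  m <- x > 0
  list(y = x * m, cache = list(m = m))
}
bwd_relu <- function(layer, cache, dy) list(dx = dy * cache$m, grads = NULL)

fwd_tanh <- function(layer, x) {
  y <- tanh(x)
  list(y = y, cache = list(y = y))
}
bwd_tanh <- function(layer, cache, dy) list(dx = dy * (1 - cache$y^2), grads = NULL)

fwd_bnorm <- function(layer, x, training) {
  n <- nrow(x)
  if (training) {
    mu <- colMeans(x)
    xc <- x - rep(mu, each = n)
    v <- colMeans(xc * xc)
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
    xc <- x - rep(mu, each = n)
  }
  istd <- 1 / sqrt(v + layer$eps)
  xhat <- xc * rep(istd, each = n)
  y <- xhat * rep(layer$gamma, each = n) + rep(layer$beta, each = n)
  list(y = y,
       cache = list(xhat = xhat, istd = istd, n = n, training = training),
       run_update = if (training) list(mean = mu, var = v) else NULL)
}

bwd_bnorm <- function(layer, cache, dy) {
  n <- cache$n
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(layer$gamma, each = n)
  if (cache$training) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dx <- rep(cache$istd, each = n) *
      (dxhat - rep(s1 / n, each = n) - cache$xhat * rep(s2 / n, each = n))
  } else {
    dx <- dxhat * rep(cache$istd, each = n)
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

fwd_maxpool <- function(layer, x, sdim) {
  H <- sdim[1]; W <- sdim[2]; N <- sdim[3]; C <- ncol(x)
  Ho <- H %/% 2L; Wo <- W %/% 2L
  a <- x; dim(a) <- c(H, W, N * C)
  i1 <- seq(1L, 2L * Ho, by = 2L); j1 <- seq(1L, 2L * Wo, by = 2L)
  a1 <- a[i1, j1, , drop = FALSE]; a2 <- a[i1 + 1L, j1, , drop = FALSE]
  a3 <- a[i1, j1 + 1L, , drop = FALSE]; a4 <- a[i1 + 1L, j1 + 1L, , drop = FALSE]
  m <- pmax(a1, a2, a3, a4)
  m1 <- a1 == m
  m2 <- (a2 == m) & !m1
  m3 <- (a3 == m) & !(m1 | m2)
  m4 <- (a4 == m) & !(m1 | m2 | m3)
  y <- m; dim(y) <- c(Ho * Wo * N, C)
  list(y = y, cache = list(m1 = m1, m2 = m2, m3 = m3, m4 = m4, i1 = i1, j1 = j1,
                           sdim = sdim, C = C, Ho = Ho, Wo = Wo),
       sdim = c(Ho, Wo, N))
}

bwd_maxpool <- function(layer, cache, dy) {
  s <- cache$sdim
  d <- dy; dim(d) <- c(cache$Ho, cache$Wo, s[3] * cache$C)
  dx <- array(0, c(s[1], s[2], s[3] * cache$C))
  i1 <- cache$i1; j1 <- cache$j1
  dx[i1, j1, ] <- d * cache$m1
  dx[i1 + 1L, j1, ] <- dx[i1 + 1L, j1, , drop = FALSE] + d * cache$m2
  dx[i1, j1 + 1L, ] <- dx[i1, j1 + 1L, , drop = FALSE] + d * cache$m3
  dx[i1 + 1L, j1 + 1L, ] <- dx[i1 + 1L, j1 + 1L, , drop = FALSE] + d * cache$m4
  dim(dx) <- c(s[1] * s[2] * s[3], cache$C)
  list(dx = dx, grads = NULL)
}

fwd_dropout <- function(layer, x, training) {
  if (!training || layer$rate <= 0)
    return(list(y = x, cache = list(mask = NULL)))
  mask <- (runif(length(x)) >= layer$rate) / (1 - layer$rate)
  dim(mask) <- dim(x)
  list(y = x * mask, cache = list(mask = mask))
}
bwd_dropout <- function(layer, cache, dy) {
  if (is.null(cache$mask)) list(dx = dy, grads = NULL)
  else list(dx = dy * cache$mask, grads = NULL)
}

# trunk (H*W*N x C) -> head (N x H*W*C); feature order is (row, col, channel)
fwd_flatten <- function(layer, x, sdim) {
  a <- x; dim(a) <- c(sdim, ncol(x))
  y <- t(matrix(aperm(a, c(1, 2, 4, 3)), sdim[1] * sdim[2] * ncol(x), sdim[3]))
  list(y = y, cache = list(sdim = sdim, C = ncol(x)), sdim = NULL)
}
bwd_flatten <- function(layer, cache, dy) {
  s <- cache$sdim
  a <- array(t(dy), c(s[1], s[2], cache$C, s[3]))
  dx <- aperm(a, c(1, 2, 4, 3))
  dim(dx) <- c(s[1] * s[2] * s[3], cache$C)
  list(dx = dx, grads = NULL)
}

fwd_dense <- function(layer, x) {
  y <- x %*% layer$W
  y <- y + rep(layer$b, each = nrow(y))
  list(y = y, cache = list(x = x))
}
bwd_dense <- function(layer, cache, dy) {
  list(dx = tcrossprod(dy, layer$W),
       grads = list(W = crossprod(cache$x, dy), b = colSums(dy)))
}

layer_forward <- function(layer, x, training, sdim) {
  switch(layer$type,
    conv = fwd_conv(layer, x, sdim),
    sepconv = fwd_sepconv(layer, x, sdim),
    relu = fwd_relu(layer, x),
    tanh = fwd_tanh(layer, x),
    bnorm = fwd_bnorm(layer, x, training),
    maxpool = fwd_maxpool(layer, x, sdim),
    dropout = fwd_dropout(layer, x, training),
    flatten = fwd_flatten(layer, x, sdim),
    dense = fwd_dense(layer, x),
    stop_wbc("wbc_layer_error", "unknown layer type %s", layer$type))
}

layer_backward <- function(layer, cache, dy, need_dx = TRUE) {
  switch(layer$type,
    conv = bwd_conv(layer, cache, dy, need_dx),
    sepconv = bwd_sepconv(layer, cache, dy, need_dx),
    relu = bwd_relu(layer, cache, dy),
    tanh = bwd_tanh(layer, cache, dy),
    bnorm = bwd_bnorm(layer, cache, dy),
    maxpool = bwd_maxpool(layer, cache, dy),
    dropout = bwd_dropout(layer, cache, dy),
    flatten = bwd_flatten(layer, cache, dy),
    dense = bwd_dense(layer, cache, dy),
    stop_wbc("wbc_layer_error", "unknown layer type %s", layer$type))
}

layer_param_names <- function(layer) {
  switch(layer$type,
    conv = c("W", "b"),
    sepconv = c("D", "P", "b"),
    bnorm = c("gamma", "beta"),
    dense = c("W", "b"),
    character(0))
}
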