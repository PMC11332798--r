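#' Training hyperparameters
#'
#' Defaults follow the full-scale training regime: Nadam with learning rate
#' 1e-5, batch size 64, 30 epochs, sparse categorical cross entropy, Glorot
#' uniform initialization. The Nadam decay constants use the canonical
#' values beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7.
#'
#' @param learning_rate step size eta (> 0).
#' @param batch_size mini-batch size.
#' @param epochs number of passes over the training set.
#' @param beta1,beta2 first/second-moment decay rates in (0, 1).
#' @param epsilon denominator stabilizer.
#' @param seed integer seed driving shuffling and dropout.
#' @return an object of class `wbc_training_params`.
#' @export
training_params <- function(learning_rate = 1e-5, batch_size = 64, epochs = 30,
                            beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7,
                            seed = 1) {
  if (learning_rate <= 0) stop_wbc("wbc_config_error", "learning_rate must be > 0")
  if (beta1 <= 0 || beta1 >= 1 || beta2 <= 0 || beta2 >= 1)
    stop_wbc("wbc_config_error", "beta1 and beta2 must lie in (0, 1)")
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 epochs = epochs, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, seed = seed),
            class = "wbc_training_params")
}

#' Initialize Nadam optimizer state
#'
#' @param params numeric vector, or list of numeric arrays, of parameters.
#' @param opts a [training_params()].
#' @return an opaque state list with zeroed first/second moments and `t = 0`.
#' @export
nadam_init <- function(params, opts = training_params()) {
  if (is.numeric(params)) params <- list(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, opts = opts)
}

#' One Nadam update step
#'
#' Nesterov-accelerated Adam. With biased moments
#' `m_t = b1 m_{t-1} + (1-b1) g_t` and `v_t = b2 v_{t-1} + (1-b2) g_t^2`,
#' and bias corrections `m^ = m_t/(1-b1^t)`, `v^ = v_t/(1-b2^t)`, the update
#' is
#' `theta <- theta - eta/(sqrt(v^) + eps) * (b1 m^ + (1-b1) g_t/(1-b1^t))`.
#' Fully deterministic.
#'
#' @param params numeric vector or list of numeric arrays.
#' @param grads gradients of the same shape.
#' @param state optimizer state from [nadam_init()] (carries the
#'   hyperparameters).
#' @return list with updated `params` and `state`.
#' @export
nadam_step <- function(params, grads, state) {
  vec_in <- is.numeric(params)
  if (vec_in) { params <- list(params); grads <- list(grads) }
  if (any(!vapply(grads, function(g) all(is.finite(g)), logical(1))))
    stop_wbc("wbc_numeric_error", "non-finite gradient in Nadam step")
  o <- state$opts
  state$t <- state$t + 1L
  t <- state$t
  bc1 <- 1 - o$beta1^t
  bc2 <- 1 - o$beta2^t
  for (i in seq_along(params)) {
    state$m[[i]] <- o$beta1 * state$m[[i]] + (1 - o$beta1) * grads[[i]]
    state$v[[i]] <- o$beta2 * state$v[[i]] + (1 - o$beta2) * grads[[i]]^2
    mhat <- state$m[[i]] / bc1
    vhat <- state$v[[i]] / bc2
    params[[i]] <- params[[i]] - o$learning_rate / (sqrt(vhat) + o$epsilon) *
      (o$beta1 * mhat + (1 - o$beta1) * grads[[i]] / bc1)
  }
  list(params = if (vec_in) params[[1]] else params, state = state)
}

# --- network-level parameter plumbing -------------------------------------

collect_params <- function(net) {
  out <- list()
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    for (p in layer_param_names(l)) out[[paste0(i, ".", p)]] <- l[[p]]
  }
  out
}

set_params <- function(net, params) {
  for (nm in names(params)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    net$layers[[as.integer(parts[1])]][[parts[2]]] <- params[[nm]]
  }
  net
}

collect_grads <- function(net, grads) {
  out <- list()
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) out[[paste0(i, ".", p)]] <- g[[p]]
  }
  out
}
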