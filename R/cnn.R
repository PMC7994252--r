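# The proposed EvoNorm 1-D CNN -------------------------------------------------

#' Configuration of the proposed 1-D convolutional network
#'
#' Two valid-padding strided 1-D convolutional layers over the time axis (32
#' filters each, kernels 13 and 6, strides 9 and 4), each preceded by an
#' EvoNorm-S0 normalization-activation layer and dropout (p = 0.5) — as is the
#' input — then a flatten and a 2-unit softmax layer. With a (201, 32) input
#' the layer shapes are (201,32) -> (21,32) -> (4,32) -> 128 -> 2.
#'
#' @param input_time input samples per trial (201 for the reference montage).
#' @param input_channels input signals (16 channels x 2 chromophores = 32).
#' @param conv_filters,kernel_sizes,strides integer pairs for the two layers.
#' @param dropout_p dropout probability.
#' @param evonorm_groups channel groups of EvoNorm-S0; must divide the channel
#'   count at every normalized layer.
#' @param norm `"evonorm"` (default) or `"batchnorm_relu"` — the ablation that
#'   replaces every EvoNorm with BatchNorm followed by ReLU.
#' @return a list of class `cnn_config`.
#' @export
cnn_config <- function(input_time = 201, input_channels = 32,
                       conv_filters = c(32, 32), kernel_sizes = c(13, 6),
                       strides = c(9, 4), dropout_p = 0.5,
                       evonorm_groups = 8, norm = c("evonorm", "batchnorm_relu")) {
  norm <- match.arg(norm)
  l1 <- conv1d_out_len(input_time, kernel_sizes[1], strides[1])
  l2 <- conv1d_out_len(l1, kernel_sizes[2], strides[2])
  structure(list(
    input_time = input_time, input_channels = input_channels,
    conv_filters = conv_filters, kernel_sizes = kernel_sizes, strides = strides,
    dropout_p = dropout_p, evonorm_groups = evonorm_groups, norm = norm,
    shape_trace = list(c(input_time, input_channels),
                       c(l1, conv_filters[1]),
                       c(l2, conv_filters[2]),
                       l2 * conv_filters[2], 2L),
    flatten_len = l2 * conv_filters[2]
  ), class = "cnn_config")
}

#' Build the proposed EvoNorm 1-D CNN
#'
#' Weights are drawn He-Normal from `seed`; EvoNorm scales start at 1, shifts
#' at 0 and gates at 1; batch-norm state (ablation variant) starts at the
#' identity transform.
#'
#' @param cfg a [cnn_config()].
#' @param seed integer seed for the weight initialization.
#' @return an untrained `nirsbci_model` of kind `"cnn"`.
#' @export
build_proposed_cnn <- function(cfg = cnn_config(), seed = 0) {
  set.seed(seed)
  ci <- cfg$input_channels
  f1 <- cfg$conv_filters[1]; f2 <- cfg$conv_filters[2]
  k1 <- cfg$kernel_sizes[1]; k2 <- cfg$kernel_sizes[2]
  params <- list(
    conv1_w = he_normal(k1 * ci, c(k1 * ci, f1)),
    conv1_b = rep(0, f1),
    conv2_w = he_normal(k2 * f1, c(k2 * f1, f2)),
    conv2_b = rep(0, f2),
    dense_w = he_normal(cfg$flatten_len, c(cfg$flatten_len, 2)),
    dense_b = rep(0, 2)
  )
  state <- list()
  for (nm in c("n0", "n1", "n2")) {
    cc <- c(ci, f1, f2)[match(nm, c("n0", "n1", "n2"))]
    if (cfg$norm == "evonorm") {
      params[[paste0(nm, "_gamma")]] <- rep(1, cc)
      params[[paste0(nm, "_beta")]] <- rep(0, cc)
      params[[paste0(nm, "_v")]] <- rep(1, cc)
    } else {
      params[[paste0(nm, "_gamma")]] <- rep(1, cc)
      params[[paste0(nm, "_beta")]] <- rep(0, cc)
      state[[nm]] <- list(mean = rep(0, cc), var = rep(1, cc))
    }
  }
  structure(list(kind = "cnn", cfg = cfg, params = params, state = state,
                 trained = FALSE, seed = seed),
            class = "nirsbci_model")
}

cnn_norm_forward <- function(model, nm, x, training) {
  p <- model$params
  if (model$cfg$norm == "evonorm") {
    en <- evonorm_forward(x, p[[paste0(nm, "_gamma")]], p[[paste0(nm, "_beta")]],
                          p[[paste0(nm, "_v")]], model$cfg$evonorm_groups)
    list(y = en$y, cache = en, state = NULL)
  } else {
    bn <- batchnorm_forward(x, p[[paste0(nm, "_gamma")]], p[[paste0(nm, "_beta")]],
                            model$state[[nm]], training)
    rl <- relu_forward(bn$y)
    list(y = rl$y, cache = list(bn = bn, rl = rl), state = bn$state)
  }
}

cnn_norm_backward <- function(model, nm, cache, dy) {
  p <- model$params
  if (model$cfg$norm == "evonorm") {
    gr <- evonorm_backward(cache, p[[paste0(nm, "_gamma")]], p[[paste0(nm, "_v")]], dy)
    g <- list(gr$dgamma, gr$dbeta, gr$dv)
    names(g) <- paste0(nm, c("_gamma", "_beta", "_v"))
    list(dx = gr$dx, grads = g)
  } else {
    dr <- relu_backward(cache$rl, dy)
    gr <- batchnorm_backward(cache$bn, p[[paste0(nm, "_gamma")]], dr)
    g <- list(gr$dgamma, gr$dbeta)
    names(g) <- paste0(nm, c("_gamma", "_beta"))
    list(dx = gr$dx, grads = g)
  }
}

cnn_forward <- function(model, x, training = FALSE) {
  cfg <- model$cfg
  p <- model$params
  caches <- list()
  n0 <- cnn_norm_forward(model, "n0", x, training)
  if (!is.null(n0$state)) model$state$n0 <- n0$state
  d0 <- dropout_forward(n0$y, cfg$dropout_p, training)
  c1 <- conv1d_forward(d0$y, p$conv1_w, p$conv1_b, cfg$kernel_sizes[1], cfg$strides[1])
  n1 <- cnn_norm_forward(model, "n1", c1$y, training)
  if (!is.null(n1$state)) model$state$n1 <- n1$state
  d1 <- dropout_forward(n1$y, cfg$dropout_p, training)
  c2 <- conv1d_forward(d1$y, p$conv2_w, p$conv2_b, cfg$kernel_sizes[2], cfg$strides[2])
  n2 <- cnn_norm_forward(model, "n2", c2$y, training)
  if (!is.null(n2$state)) model$state$n2 <- n2$state
  d2 <- dropout_forward(n2$y, cfg$dropout_p, training)
  fl <- flatten_forward(d2$y)
  de <- dense_forward(fl$y, p$dense_w, p$dense_b)
  list(logits = de$y, model = model,
       cache = list(n0 = n0$cache, d0 = d0, c1 = c1, n1 = n1$cache, d1 = d1,
                    c2 = c2, n2 = n2$cache, d2 = d2, fl = fl, de = de))
}

cnn_backward <- function(model, cache, dlogits) {
  p <- model$params
  grads <- list()
  de <- dense_backward(cache$de, p$dense_w, dlogits)
  grads$dense_w <- de$dw; grads$dense_b <- de$db
  g <- flatten_backward(cache$fl, de$dx)
  g <- dropout_backward(cache$d2, g)
  n2 <- cnn_norm_backward(model, "n2", cache$n2, g)
  grads <- c(grads, n2$grads)
  c2 <- conv1d_backward(cache$c2, p$conv2_w, n2$dx)
  grads$conv2_w <- c2$dw; grads$conv2_b <- c2$db
  g <- dropout_backward(cache$d1, c2$dx)
  n1 <- cnn_norm_backward(model, "n1", cache$n1, g)
  grads <- c(grads, n1$grads)
  c1 <- conv1d_backward(cache$c1, p$conv1_w, n1$dx)
  grads$conv1_w <- c1$dw; grads$conv1_b <- c1$db
  g <- dropout_backward(cache$d0, c1$dx)
  n0 <- cnn_norm_backward(model, "n0", cache$n0, g)
  grads <- c(grads, n0$grads)
  grads
}

#' Layer-shape trace of a model
#'
#' @param model a `nirsbci_model` (or its config).
#' @return list of output shapes, input through the softmax layer.
#' @export
shape_trace <- function(model) {
  cfg <- if (inherits(model, "nirsbci_model")) model$cfg else model
  cfg$shape_trace
}

#' Number of trainable parameters of a model
#'
#' @param model a `nirsbci_model`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}
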