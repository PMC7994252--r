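# EEGNet comparison architecture ------------------------------------------------

#' Configuration of the EEGNet comparison network
#'
#' The compact convolutional architecture with a temporal convolution (F1
#' filters, kernel (1, 6) — half the sampling rate), a depthwise spatial
#' convolution spanning all input rows (kernel (32, 1), depth multiplier D,
#' max-norm 1), and a separable convolution (F2 filters, kernel (1, 2)),
#' each followed by batch normalization and (after the spatial and separable
#' stages) ELU, average pooling ((1,4) then (1,8)) and dropout (p = 0.25),
#' ending in a flatten (6 x F2 = 96) and a 2-unit softmax.
#'
#' With an input of 32 rows x 201 samples the shape trace is
#' (32,201,1) -> (32,201,8) -> (1,201,16) -> (1,50,16) -> (1,50,16)
#' -> (1,6,16) -> 96 -> 2.
#'
#' @param input_rows input rows (16 channels x 2 chromophores = 32).
#' @param input_time time samples (201).
#' @param f1 temporal filters.
#' @param d depth multiplier of the depthwise stage.
#' @param f2 separable filters.
#' @param temporal_kernel,separable_kernel kernel lengths along time.
#' @param pools the two average-pooling widths.
#' @param dropout_p dropout probability.
#' @return a list of class `eegnet_config`.
#' @export
eegnet_config <- function(input_rows = 32, input_time = 201, f1 = 8, d = 2,
                          f2 = 16, temporal_kernel = 6, separable_kernel = 2,
                          pools = c(4, 8), dropout_p = 0.25) {
  t1 <- input_time %/% pools[1]
  t2 <- t1 %/% pools[2]
  structure(list(
    input_rows = input_rows, input_time = input_time,
    f1 = f1, d = d, f2 = f2,
    temporal_kernel = temporal_kernel, separable_kernel = separable_kernel,
    pools = pools, dropout_p = dropout_p,
    shape_trace = list(c(input_rows, input_time, 1L),
                       c(input_rows, input_time, f1),
                       c(1L, input_time, f1 * d),
                       c(1L, t1, f1 * d),
                       c(1L, t1, f2),
                       c(1L, t2, f2),
                       t2 * f2, 2L),
    flatten_len = t2 * f2
  ), class = "eegnet_config")
}

#' Build the EEGNet comparison network
#'
#' Convolutions carry no bias (as in the reference implementation); weights
#' are Glorot-uniform from `seed`; the depthwise kernels are re-projected to
#' max-norm 1 after every optimizer step.
#'
#' @param cfg an [eegnet_config()].
#' @param seed integer seed for the weight initialization.
#' @return an untrained `nirsbci_model` of kind `"eegnet"`.
#' @export
build_eegnet <- function(cfg = eegnet_config(), seed = 0) {
  set.seed(seed)
  params <- list(
    convt_w = glorot_uniform(cfg$temporal_kernel, cfg$f1,
                             c(cfg$temporal_kernel, cfg$f1)),
    bn1_gamma = rep(1, cfg$f1), bn1_beta = rep(0, cfg$f1),
    dw_w = glorot_uniform(cfg$input_rows, cfg$d,
                          c(cfg$input_rows, cfg$f1, cfg$d)),
    bn2_gamma = rep(1, cfg$f1 * cfg$d), bn2_beta = rep(0, cfg$f1 * cfg$d),
    sep_dw = glorot_uniform(cfg$separable_kernel, 1,
                            c(cfg$separable_kernel, cfg$f1 * cfg$d)),
    sep_pw = glorot_uniform(cfg$f1 * cfg$d, cfg$f2, c(cfg$f1 * cfg$d, cfg$f2)),
    bn3_gamma = rep(1, cfg$f2), bn3_beta = rep(0, cfg$f2),
    dense_w = glorot_uniform(cfg$flatten_len, 2, c(cfg$flatten_len, 2)),
    dense_b = rep(0, 2)
  )
  state <- list(
    bn1 = list(mean = rep(0, cfg$f1), var = rep(1, cfg$f1)),
    bn2 = list(mean = rep(0, cfg$f1 * cfg$d), var = rep(1, cfg$f1 * cfg$d)),
    bn3 = list(mean = rep(0, cfg$f2), var = rep(1, cfg$f2))
  )
  structure(list(kind = "eegnet", cfg = cfg, params = params, state = state,
                 trained = FALSE, seed = seed),
            class = "nirsbci_model")
}

# x arrives as the epoch tensor (B, T, C); EEGNet treats the signals as image
# rows: (B, rows = C, time = T).
eegnet_forward <- function(model, x, training = FALSE) {
  cfg <- model$cfg
  p <- model$params
  d <- dim(x)
  stopifnot(d[2] == cfg$input_time, d[3] == cfg$input_rows)
  xr <- aperm(x, c(1, 3, 2)) # (B, rows, T)
  b <- d[1]
  xm <- xr
  dim(xm) <- c(b * cfg$input_rows, cfg$input_time)
  ct <- conv_rows_same_forward(xm, p$convt_w) # (B*rows, T, F1)
  h1 <- ct$y
  dim(h1) <- c(b, cfg$input_rows, cfg$input_time, cfg$f1)
  bn1 <- batchnorm_forward(h1, p$bn1_gamma, p$bn1_beta, model$state$bn1, training)
  model$state$bn1 <- bn1$state
  dw <- dw_collapse_forward(bn1$y, p$dw_w) # (B, T, F1*D)
  bn2 <- batchnorm_forward(dw$y, p$bn2_gamma, p$bn2_beta, model$state$bn2, training)
  model$state$bn2 <- bn2$state
  e2 <- elu_forward(bn2$y)
  p1 <- avgpool_forward(e2$y, cfg$pools[1]) # (B, 50, 16)
  do1 <- dropout_forward(p1$y, cfg$dropout_p, training)
  sd <- dw_time_same_forward(do1$y, p$sep_dw)
  sp <- pointwise_forward(sd$y, p$sep_pw) # (B, 50, F2)
  bn3 <- batchnorm_forward(sp$y, p$bn3_gamma, p$bn3_beta, model$state$bn3, training)
  model$state$bn3 <- bn3$state
  e3 <- elu_forward(bn3$y)
  p2 <- avgpool_forward(e3$y, cfg$pools[2]) # (B, 6, F2)
  do2 <- dropout_forward(p2$y, cfg$dropout_p, training)
  fl <- flatten_forward(do2$y)
  de <- dense_forward(fl$y, p$dense_w, p$dense_b)
  list(logits = de$y, model = model,
       cache = list(b = b, ct = ct, bn1 = bn1, dw = dw, bn2 = bn2, e2 = e2,
                    p1 = p1, do1 = do1, sd = sd, sp = sp, bn3 = bn3, e3 = e3,
                    p2 = p2, do2 = do2, fl = fl, de = de))
}

eegnet_backward <- function(model, cache, dlogits) {
  cfg <- model$cfg
  p <- model$params
  grads <- list()
  de <- dense_backward(cache$de, p$dense_w, dlogits)
  grads$dense_w <- de$dw; grads$dense_b <- de$db
  g <- flatten_backward(cache$fl, de$dx)
  g <- dropout_backward(cache$do2, g)
  g <- avgpool_backward(cache$p2, g)
  g <- elu_backward(cache$e3, g)
  b3 <- batchnorm_backward(cache$bn3, p$bn3_gamma, g)
  grads$bn3_gamma <- b3$dgamma; grads$bn3_beta <- b3$dbeta
  spb <- pointwise_backward(cache$sp, p$sep_pw, b3$dx)
  grads$sep_pw <- spb$dw
  sdb <- dw_time_same_backward(cache$sd, p$sep_dw, spb$dx)
  grads$sep_dw <- sdb$dw
  g <- dropout_backward(cache$do1, sdb$dx)
  g <- avgpool_backward(cache$p1, g)
  g <- elu_backward(cache$e2, g)
  b2 <- batchnorm_backward(cache$bn2, p$bn2_gamma, g)
  grads$bn2_gamma <- b2$dgamma; grads$bn2_beta <- b2$dbeta
  dwb <- dw_collapse_backward(cache$dw, p$dw_w, b2$dx)
  grads$dw_w <- dwb$dw
  b1 <- batchnorm_backward(cache$bn1, p$bn1_gamma, dwb$dx)
  grads$bn1_gamma <- b1$dgamma; grads$bn1_beta <- b1$dbeta
  g <- b1$dx # (B, rows, T, F1)
  dim(g) <- c(cache$b * cfg$input_rows, cfg$input_time, cfg$f1)
  ctb <- conv_rows_same_backward(cache$ct, p$convt_w, g)
  grads$convt_w <- ctb$dw
  grads
}

# Re-project the depthwise spatial kernels onto the max-norm-1 ball.
eegnet_maxnorm <- function(params, max_norm = 1) {
  w <- params$dw_w
  for (f in seq_len(dim(w)[2])) {
    for (dd in seq_len(dim(w)[3])) {
      nrm <- sqrt(sum(w[, f, dd]^2))
      if (nrm > max_norm) w[, f, dd] <- w[, f, dd] * (max_norm / nrm)
    }
  }
  params$dw_w <- w
  params
}
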