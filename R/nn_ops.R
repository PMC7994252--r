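# Low-level neural-network operations -----------------------------------------
#
# Tensors follow the convention (batch, time, channels) stored as base-R
# arrays (column-major). Every forward op returns the values it needs for the
# analytic backward pass; gradients are checked against finite differences in
# the test suite.

he_normal <- function(fan_in, dims) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

glorot_uniform <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# broadcast a per-channel vector over (B, T, C)
bc_channel <- function(vec, d) {
  out <- rep(vec, each = d[1] * d[2])
  dim(out) <- d
  out
}

# broadcast a (B, groups) matrix over (B, T, C) with contiguous channel groups
bc_group <- function(mat, d, groups) {
  cs <- d[3] / groups
  dm <- mat[, rep(seq_len(groups), each = cs), drop = FALSE] # (B, C)
  out <- dm[, rep(seq_len(d[3]), each = d[2]), drop = FALSE]
  dim(out) <- d
  out
}

# reduce (B, T, C) to per-channel sums
reduce_channel <- function(arr) {
  d <- dim(arr)
  dim(arr) <- c(d[1] * d[2], d[3])
  colSums(arr)
}

# reduce (B, T, C) to (B, groups) sums over contiguous channel groups
reduce_group <- function(arr, groups) {
  d <- dim(arr)
  cs <- d[3] / groups
  dim(arr) <- c(d[1], d[2] * cs, groups)
  ap <- aperm(arr, c(2, 1, 3))
  dim(ap) <- c(d[2] * cs, d[1] * groups)
  matrix(colSums(ap), d[1], groups)
}

#' Output length of a valid-padding strided 1-D convolution
#'
#' @param n_in input length.
#' @param kernel kernel size (`<= n_in`).
#' @param stride stride (`>= 1`).
#' @return `floor((n_in - kernel) / stride) + 1`.
#' @export
conv1d_out_len <- function(n_in, kernel, stride) {
  stopifnot(kernel >= 1, stride >= 1)
  if (kernel > n_in) stop("kernel larger than the input length", call. = FALSE)
  as.integer(floor((n_in - kernel) / stride) + 1)
}

# Valid-padding strided 1-D convolution over the time axis.
# x: (B, T, Cin); w: (k*Cin, Cout) rows ordered kernel-position fastest;
# b: (Cout). Returns y (B, L, Cout) and the patch matrix for backward.
conv1d_forward <- function(x, w, b, kernel, stride) {
  d <- dim(x)
  L <- conv1d_out_len(d[2], kernel, stride)
  idx <- outer(seq_len(L) - 1L, seq_len(kernel), function(l, j) l * stride + j)
  p <- x[, as.vector(idx), , drop = FALSE] # (B, L*k, C), l fastest
  dim(p) <- c(d[1] * L, kernel * d[3])
  y <- p %*% w
  y <- sweep(y, 2, b, "+")
  dim(y) <- c(d[1], L, ncol(w))
  list(y = y, p = p, idx = idx, in_dim = d)
}

conv1d_backward <- function(cache, w, dy) {
  d <- cache$in_dim
  L <- nrow(cache$idx)
  kernel <- ncol(cache$idx)
  cout <- dim(dy)[3]
  dym <- dy
  dim(dym) <- c(d[1] * L, cout)
  dw <- crossprod(cache$p, dym)
  db <- colSums(dym)
  dp <- dym %*% t(w) # (B*L, k*C)
  dim(dp) <- c(d[1], L, kernel, d[3])
  dx <- array(0, dim = d)
  for (j in seq_len(kernel)) {
    dx[, cache$idx[, j], ] <- dx[, cache$idx[, j], ] + dp[, , j, ]
  }
  list(dx = dx, dw = dw, db = db)
}

tf_same_pad <- function(kernel) {
  total <- kernel - 1L
  c(left = total %/% 2L, right = total - total %/% 2L)
}

# Stride-1 same-padding convolution of independent rows (single input channel).
# x: (N, T); w: (k, F). Returns y (N, T, F).
conv_rows_same_forward <- function(x, w) {
  k <- nrow(w)
  pad <- tf_same_pad(k)
  n <- nrow(x); tt <- ncol(x)
  xp <- cbind(matrix(0, n, pad["left"]), x, matrix(0, n, pad["right"]))
  idx <- outer(seq_len(tt) - 1L, seq_len(k), function(t, j) t + j)
  p <- xp[, as.vector(idx), drop = FALSE]
  dim(p) <- c(n * tt, k)
  y <- p %*% w
  dim(y) <- c(n, tt, ncol(w))
  list(y = y, p = p, idx = idx, n = n, t = tt, pad = pad)
}

conv_rows_same_backward <- function(cache, w, dy) {
  k <- nrow(w)
  dym <- dy
  dim(dym) <- c(cache$n * cache$t, ncol(w))
  dw <- crossprod(cache$p, dym)
  dp <- dym %*% t(w)
  dim(dp) <- c(cache$n, cache$t, k)
  dxp <- matrix(0, cache$n, cache$t + k - 1L)
  for (j in seq_len(k)) {
    cols <- seq_len(cache$t) + j - 1L
    dxp[, cols] <- dxp[, cols] + dp[, , j]
  }
  dx <- dxp[, cache$pad["left"] + seq_len(cache$t), drop = FALSE]
  list(dx = dx, dw = dw)
}

# Depthwise convolution collapsing the spatial (height) axis.
# x: (B, H, T, F); w: (H, F, D). Returns y (B, T, F*D), channels ordered
# (f-1)*D + d (input-channel-major, depth fastest) as in Keras.
dw_collapse_forward <- function(x, w) {
  d <- dim(x)
  depth <- dim(w)[3]
  nf <- dim(w)[2]
  xp <- aperm(x, c(1, 3, 2, 4)) # (B, T, H, F), one transpose for all filters
  dim(xp) <- c(d[1] * d[3], d[2], nf)
  y <- array(0, dim = c(d[1], d[3], nf * depth))
  for (f in seq_len(nf)) {
    y[, , (f - 1) * depth + seq_len(depth)] <-
      array(xp[, , f] %*% w[, f, ], dim = c(d[1], d[3], depth))
  }
  list(y = y, xp = xp, in_dim = d)
}

dw_collapse_backward <- function(cache, w, dy) {
  d <- cache$in_dim
  depth <- dim(w)[3]
  nf <- dim(w)[2]
  dw <- array(0, dim = dim(w))
  dxp <- array(0, dim = c(d[1] * d[3], d[2], nf))
  for (f in seq_len(nf)) {
    dyf <- dy[, , (f - 1) * depth + seq_len(depth), drop = FALSE]
    dim(dyf) <- c(d[1] * d[3], depth)
    dw[, f, ] <- crossprod(cache$xp[, , f], dyf)
    dxp[, , f] <- dyf %*% t(w[, f, ])
  }
  dim(dxp) <- c(d[1], d[3], d[2], nf)
  list(dx = aperm(dxp, c(1, 3, 2, 4)), dw = dw)
}

# Depthwise stride-1 same-padding convolution over time, one kernel per channel.
# x: (B, T, C); w: (k, C).
dw_time_same_forward <- function(x, w) {
  d <- dim(x)
  k <- nrow(w)
  pad <- tf_same_pad(k)
  xp <- array(0, dim = c(d[1], d[2] + k - 1L, d[3]))
  xp[, pad["left"] + seq_len(d[2]), ] <- x
  y <- array(0, dim = d)
  for (j in seq_len(k)) {
    y <- y + xp[, j + seq_len(d[2]) - 1L, , drop = FALSE] * bc_channel(w[j, ], d)
  }
  list(y = y, xp = xp, pad = pad, k = k, in_dim = d)
}

dw_time_same_backward <- function(cache, w, dy) {
  d <- cache$in_dim
  k <- cache$k
  dw <- matrix(0, k, d[3])
  dxp <- array(0, dim = dim(cache$xp))
  for (j in seq_len(k)) {
    xs <- cache$xp[, j + seq_len(d[2]) - 1L, , drop = FALSE]
    dw[j, ] <- reduce_channel(dy * xs)
    dxp[, j + seq_len(d[2]) - 1L, ] <- dxp[, j + seq_len(d[2]) - 1L, ] +
      dy * bc_channel(w[j, ], d)
  }
  dx <- dxp[, cache$pad["left"] + seq_len(d[2]), , drop = FALSE]
  list(dx = dx, dw = dw)
}

# Pointwise (1x1) convolution: x (B, T, Cin), w (Cin, Cout).
pointwise_forward <- function(x, w) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3])
  y <- xm %*% w
  dim(y) <- c(d[1], d[2], ncol(w))
  list(y = y, xm = xm, in_dim = d)
}

pointwise_backward <- function(cache, w, dy) {
  d <- cache$in_dim
  dym <- dy
  dim(dym) <- c(d[1] * d[2], ncol(w))
  dw <- crossprod(cache$xm, dym)
  dx <- dym %*% t(w)
  dim(dx) <- d
  list(dx = dx, dw = dw)
}

# EvoNorm-S0 over (B, T, C): y = x * sigmoid(v*x) / group_std(x) * gamma + beta
evonorm_forward <- function(x, gamma, beta, v, groups, eps = 1e-5) {
  d <- dim(x)
  stopifnot(d[3] %% groups == 0)
  n <- d[2] * d[3] / groups
  mu <- reduce_group(x, groups) / n
  ex2 <- reduce_group(x * x, groups) / n
  dstd <- sqrt(ex2 - mu^2 + eps)
  vf <- bc_channel(v, d)
  sig <- 1 / (1 + exp(-vf * x))
  num <- x * sig
  df <- bc_group(dstd, d, groups)
  y <- num / df * bc_channel(gamma, d) + bc_channel(beta, d)
  list(y = y, x = x, sig = sig, num = num, df = df, mu = mu, dstd = dstd,
       n = n, groups = groups)
}

evonorm_backward <- function(cache, gamma, v, dy) {
  x <- cache$x
  d <- dim(x)
  gf <- bc_channel(gamma, d)
  dgamma <- reduce_channel(dy * cache$num / cache$df)
  dbeta <- reduce_channel(dy)
  dnum <- dy * gf / cache$df
  dd <- reduce_group(dy * gf * cache$num * (-1 / cache$df^2), cache$groups)
  vf <- bc_channel(v, d)
  dv <- reduce_channel(dnum * x^2 * cache$sig * (1 - cache$sig))
  dx_num <- dnum * cache$sig * (1 + vf * x * (1 - cache$sig))
  muf <- bc_group(cache$mu, d, cache$groups)
  dx_std <- bc_group(dd, d, cache$groups) * (x - muf) / (cache$n * cache$df)
  list(dx = dx_num + dx_std, dgamma = dgamma, dbeta = dbeta, dv = dv)
}

# Batch normalization over the last (channel) axis of an arbitrary array.
# The channel count is small and the row count huge, so everything runs as a
# per-channel column loop (no full-size broadcast temporaries).
batchnorm_forward <- function(x, gamma, beta, state, training,
                              momentum = 0.99, eps = 1e-3) {
  d <- dim(x)
  cc <- d[length(d)]
  m <- prod(d) / cc
  xm <- x
  dim(xm) <- c(m, cc)
  xhat <- matrix(0, m, cc)
  y <- matrix(0, m, cc)
  istd <- numeric(cc)
  if (training) {
    mu <- .colMeans(xm, m, cc)
    var <- numeric(cc)
    for (j in seq_len(cc)) {
      v <- xm[, j] - mu[j]
      var[j] <- sum(v * v) / m
      istd[j] <- 1 / sqrt(var[j] + eps)
      xhat[, j] <- v * istd[j]
      y[, j] <- xhat[, j] * gamma[j] + beta[j]
    }
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * var
  } else {
    for (j in seq_len(cc)) {
      istd[j] <- 1 / sqrt(state$var[j] + eps)
      xhat[, j] <- (xm[, j] - state$mean[j]) * istd[j]
      y[, j] <- xhat[, j] * gamma[j] + beta[j]
    }
  }
  dim(y) <- d
  list(y = y, xhat = xhat, istd = istd, m = m, d = d, cc = cc,
       state = state, training = training)
}

batchnorm_backward <- function(cache, gamma, dy) {
  d <- cache$d
  m <- cache$m
  cc <- cache$cc
  dym <- dy
  dim(dym) <- c(m, cc)
  dgamma <- numeric(cc)
  dbeta <- numeric(cc)
  dx <- matrix(0, m, cc)
  for (j in seq_len(cc)) {
    dyj <- dym[, j]
    xh <- cache$xhat[, j]
    dgamma[j] <- sum(dyj * xh)
    dbeta[j] <- sum(dyj)
    if (cache$training) {
      dxh <- dyj * gamma[j]
      dx[, j] <- (dxh - sum(dxh) / m - xh * (sum(dxh * xh) / m)) * cache$istd[j]
    } else {
      dx[, j] <- dyj * (gamma[j] * cache$istd[j])
    }
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

elu_forward <- function(x, alpha = 1) {
  neg <- x <= 0
  y <- x
  y[neg] <- alpha * (exp(x[neg]) - 1)
  list(y = y, neg = neg, yneg = y[neg], alpha = alpha)
}

elu_backward <- function(cache, dy) {
  g <- dy
  g[cache$neg] <- dy[cache$neg] * (cache$yneg + cache$alpha)
  g
}

relu_forward <- function(x) {
  y <- pmax(x, 0)
  dim(y) <- dim(x)
  list(y = y, mask = x > 0)
}

relu_backward <- function(cache, dy) {
  g <- dy
  g[!cache$mask] <- 0
  g
}

# Inverted dropout; uses the current RNG stream (seeded by the trainer).
dropout_forward <- function(x, p, training) {
  if (!training || p <= 0) {
    return(list(y = x, mask = NULL))
  }
  mask <- array((stats::runif(length(x)) >= p) / (1 - p), dim = dim(x))
  list(y = x * mask, mask = mask)
}

dropout_backward <- function(cache, dy) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

# Non-overlapping average pooling over the time axis; tail samples beyond the
# last full window are discarded (TF "valid" pooling).
avgpool_forward <- function(x, pool) {
  d <- dim(x)
  to <- d[2] %/% pool
  xt <- x[, seq_len(to * pool), , drop = FALSE]
  dim(xt) <- c(d[1], pool, to, d[3])
  ap <- aperm(xt, c(2, 1, 3, 4))
  dim(ap) <- c(pool, d[1] * to * d[3])
  y <- array(colMeans(ap), dim = c(d[1], to, d[3]))
  list(y = y, pool = pool, in_dim = d, to = to)
}

avgpool_backward <- function(cache, dy) {
  d <- cache$in_dim
  dx <- array(0, dim = d)
  share <- dy / cache$pool
  for (j in seq_len(cache$pool)) {
    dx[, j + cache$pool * (seq_len(cache$to) - 1L), ] <- share
  }
  dx
}

# Flatten (B, T, C) to (B, C*T) with the channel index fastest (Keras order).
flatten_forward <- function(x) {
  d <- dim(x)
  y <- aperm(x, c(1, 3, 2))
  dim(y) <- c(d[1], d[2] * d[3])
  list(y = y, in_dim = d)
}

flatten_backward <- function(cache, dy) {
  d <- cache$in_dim
  dim(dy) <- c(d[1], d[3], d[2])
  aperm(dy, c(1, 3, 2))
}

dense_forward <- function(x, w, b) {
  y <- sweep(x %*% w, 2, b, "+")
  list(y = y, x = x)
}

dense_backward <- function(cache, w, dy) {
  list(dx = dy %*% t(w), dw = crossprod(cache$x, dy), db = colSums(dy))
}

softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Categorical cross-entropy; y01 is the 0/1 MA indicator per row.
softmax_ce <- function(logits, y01) {
  p <- softmax(logits)
  yk <- cbind(1 - y01, y01)
  eps <- 1e-12
  loss <- -mean(log(pmax(rowSums(p * yk), eps)))
  dlogits <- (p - yk) / nrow(p)
  list(loss = loss, probs = p, dlogits = dlogits)
}

# Adamax optimizer (infinity-norm Adam variant) with legacy per-update
# learning-rate decay lr_t = lr / (1 + decay * t).
adamax_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    u = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    t = 0L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamax_step <- function(params, grads, opt, lr = 5e-4, decay = 5e-8,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  opt$t <- opt$t + 1L
  lr_t <- lr / (1 + decay * (opt$t - 1L))
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$u[[nm]] <- pmax(beta2 * opt$u[[nm]], abs(g))
    step <- lr_t / (1 - beta1^opt$t) * opt$m[[nm]] / (opt$u[[nm]] + eps)
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, opt = opt)
}
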