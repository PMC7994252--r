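test_that("valid-convolution output lengths match the architecture table", {
  expect_equal(conv1d_out_len(201, 13, 9), 21L)
  expect_equal(conv1d_out_len(21, 6, 4), 4L)
  for (k in c(1, 5, 13)) expect_equal(conv1d_out_len(k, k, 3), 1L)
  expect_error(conv1d_out_len(5, 6, 1), "kernel")
})

test_that("the proposed CNN layer-shape trace is (201,32)->(21,32)->(4,32)->128->2", {
  tr <- shape_trace(cnn_config())
  expect_equal(tr[[1]], c(201, 32))
  expect_equal(tr[[2]], c(21, 32))
  expect_equal(tr[[3]], c(4, 32))
  expect_equal(tr[[4]], 128)
  expect_equal(tr[[5]], 2L)
})

test_that("the EEGNet layer-shape trace matches the reference table with F1=8, D=2, F2=16", {
  tr <- shape_trace(eegnet_config())
  expect_equal(tr[[1]], c(32L, 201L, 1L))
  expect_equal(tr[[2]], c(32L, 201L, 8L))
  expect_equal(tr[[3]], c(1L, 201L, 16L))  # depthwise collapses the rows
  expect_equal(tr[[4]], c(1L, 50L, 16L))
  expect_equal(tr[[5]], c(1L, 50L, 16L))
  expect_equal(tr[[6]], c(1L, 6L, 16L))
  expect_equal(tr[[7]], 96L)
  expect_equal(tr[[8]], 2L)
})

test_that("the proposed CNN parameter count is frozen", {
  m <- build_proposed_cnn(cnn_config(), seed = 0)
  # conv1 32*13*32+32, conv2 32*6*32+32, dense 128*2+2, 3 EvoNorm layers a 3*32
  expect_equal(n_parameters(m), 13344 + 6176 + 258 + 3 * 96)
})

test_that("initialization is deterministic in the seed", {
  a <- build_proposed_cnn(cnn_config(), seed = 0)
  b <- build_proposed_cnn(cnn_config(), seed = 0)
  cc <- build_proposed_cnn(cnn_config(), seed = 1)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params$conv1_w, cc$params$conv1_w))
  e1 <- build_eegnet(eegnet_config(), seed = 0)
  e2 <- build_eegnet(eegnet_config(), seed = 0)
  expect_identical(e1$params, e2$params)
})

test_that("softmax outputs are probabilities on random inputs", {
  set.seed(20)
  m <- build_proposed_cnn(cnn_config(), seed = 0)
  x <- array(rnorm(4 * 201 * 32), c(4, 201, 32))
  p <- softmax(nirsbci:::cnn_forward(m, x, training = FALSE)$logits)
  expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
  expect_true(all(p >= 0))
})

test_that("EvoNorm-S0 reduces to 0.5*x/std(x) at v=0, gamma=1, beta=0, groups=1", {
  set.seed(21)
  x <- array(rnorm(3 * 40 * 4), c(3, 40, 4))
  out <- nirsbci:::evonorm_forward(x, gamma = rep(1, 4), beta = rep(0, 4),
                                   v = rep(0, 4), groups = 1)
  ref <- x
  for (b in 1:3) {
    v <- x[b, , ]
    ref[b, , ] <- 0.5 * v / sqrt(mean((v - mean(v))^2) + 1e-5)
  }
  expect_lt(max(abs(out$y - ref)), 1e-6)
})

test_that("analytic gradients match finite differences (both architectures)", {
  set.seed(22)
  check <- function(kind) {
    if (kind == "cnn") {
      cfg <- cnn_config(input_time = 30, input_channels = 8,
                        kernel_sizes = c(5, 3), strides = c(3, 2),
                        evonorm_groups = 4, dropout_p = 0)
      model <- build_proposed_cnn(cfg, seed = 1)
      tt <- 30
    } else {
      cfg <- eegnet_config(input_rows = 8, input_time = 40, f1 = 4, d = 2,
                           f2 = 8, pools = c(4, 2))
      model <- build_eegnet(cfg, seed = 1)
      model$cfg$dropout_p <- 0
      tt <- 40
    }
    x <- array(rnorm(3 * tt * 8), c(3, tt, 8))
    y01 <- c(1, 0, 1)
    loss_fn <- function(m) {
      fw <- nirsbci:::model_forward(m, x, training = TRUE)
      nirsbci:::softmax_ce(fw$logits, y01)$loss
    }
    fw <- nirsbci:::model_forward(model, x, training = TRUE)
    sc <- nirsbci:::softmax_ce(fw$logits, y01)
    gr <- nirsbci:::model_backward(fw$model, fw$cache, sc$dlogits)
    for (nm in names(model$params)) {
      p <- model$params[[nm]]
      for (i in sample(length(p), min(3, length(p)))) {
        eps <- 1e-5
        mp <- model; mp$params[[nm]][i] <- p[i] + eps
        mm <- model; mm$params[[nm]][i] <- p[i] - eps
        ng <- (loss_fn(mp) - loss_fn(mm)) / (2 * eps)
        expect_lt(abs(ng - gr[[nm]][i]),
                  1e-6 + 1e-4 * (abs(ng) + abs(gr[[nm]][i])))
      }
    }
  }
  check("cnn")
  check("eegnet")
})

test_that("the BatchNorm+ReLU ablation of the proposed CNN builds and trains", {
  set.seed(23)
  ep <- separable_epochs(n_trials = 40, n_time = 30, n_signals = 8)
  epz <- zscore_time(ep)
  cfg <- cnn_config(input_time = 30, input_channels = 8,
                    kernel_sizes = c(5, 3), strides = c(3, 2),
                    evonorm_groups = 4, norm = "batchnorm_relu")
  m <- train_network(build_proposed_cnn(cfg, 0), epz,
                     train_spec(max_epochs = 5, batch_size = 20))
  expect_true(m$trained)
  expect_equal(nrow(m$log$history), 5)
  p <- predict_proba(m, epz)
  expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
})

test_that("depthwise max-norm projection caps each spatial kernel at norm 1", {
  m <- build_eegnet(eegnet_config(), seed = 0)
  m$params$dw_w <- m$params$dw_w * 10
  pp <- nirsbci:::eegnet_maxnorm(m$params)
  for (f in seq_len(dim(pp$dw_w)[2])) {
    for (dd in seq_len(dim(pp$dw_w)[3])) {
      expect_lte(sqrt(sum(pp$dw_w[, f, dd]^2)), 1 + 1e-12)
    }
  }
})
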