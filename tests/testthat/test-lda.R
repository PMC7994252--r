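test_that("symmetric one-dimensional classes put the boundary at zero", {
  x <- matrix(c(-1.2, -1, -0.8, 0.8, 1, 1.2), ncol = 1)
  fm <- feature_matrix(x, c("IS", "IS", "IS", "MA", "MA", "MA"))
  m <- fit_slda(fm, shrinkage = 0)
  expect_lt(abs(m$bias / m$weights[1]), 1e-12) # boundary at x = 0
  expect_equal(as.character(predict_lda(m, matrix(c(-0.1, 0.1), ncol = 1))),
               c("IS", "MA"))
})

test_that("full shrinkage reduces to the nearest-class-mean direction", {
  set.seed(10)
  x <- rbind(matrix(rnorm(40, sd = 2), 20, 2),
             sweep(matrix(rnorm(40, sd = 0.5), 20, 2), 2, c(2, -1), "+"))
  fm <- feature_matrix(x, rep(c("IS", "MA"), each = 20))
  m <- fit_slda(fm, shrinkage = 1)
  st <- nirsbci:::pooled_class_stats(fm$values, fm$labels)
  nu <- mean(diag(st$sigma))
  expect_equal(m$weights, as.numeric((st$mu1 - st$mu0) / nu), tolerance = 1e-10)
})

test_that("gamma = 0.1 weights match a hand-computed 2x2 solve on a fixed toy", {
  # hand-listed points, 4 per class
  x <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1),
             c(3, 2), c(4, 2), c(3, 3), c(4, 3))
  y <- rep(c("IS", "MA"), each = 4)
  m <- fit_slda(feature_matrix(x, y), shrinkage = 0.1)
  # oracle: mu0=(0.5,0.5), mu1=(3.5,2.5); pooled cov = diag(1/3, 1/3);
  # nu = 1/3; sigma_g = 0.9*S + 0.1*nu*I = diag(1/3); w = 3*(3, 2); b = -w'(2,1.5)
  expect_equal(m$weights, c(9, 6), tolerance = 1e-10)
  expect_equal(m$bias, -(9 * 2 + 6 * 1.5), tolerance = 1e-10)
})

test_that("zero shrinkage equals an independent Fisher LDA implementation", {
  set.seed(12)
  for (p in 2:3) {
    x <- rbind(matrix(rnorm(30 * p), 30),
               sweep(matrix(rnorm(30 * p), 30), 2, seq_len(p), "+"))
    y01 <- rep(0:1, each = 30)
    m <- fit_slda(feature_matrix(x, ifelse(y01 == 1, "MA", "IS")), shrinkage = 0)
    or <- oracle_fisher_lda(x, y01)
    expect_equal(m$weights, or$w, tolerance = 1e-8)
    expect_equal(m$bias, or$b, tolerance = 1e-8)
  }
})

test_that("the shrinkage path is continuous with no sign flips on separated data", {
  set.seed(13)
  x <- rbind(matrix(rnorm(40, sd = 0.3), 20, 2),
             sweep(matrix(rnorm(40, sd = 0.3), 20, 2), 2, c(3, 3), "+"))
  fm <- feature_matrix(x, rep(c("IS", "MA"), each = 20))
  gammas <- seq(0, 1, by = 0.05)
  ws <- t(vapply(gammas, function(g) fit_slda(fm, g)$weights, numeric(2)))
  mu_diff <- colMeans(x[21:40, ]) - colMeans(x[1:20, ])
  proj <- ws %*% mu_diff
  expect_true(all(proj > 0))
  steps <- sqrt(rowSums(diff(ws)^2))
  expect_lt(max(steps), 0.5 * max(sqrt(rowSums(ws^2))))
})

test_that("analytic shrinkage intensity stays in [0,1] and grows as n shrinks", {
  set.seed(14)
  p <- 10
  a <- matrix(rnorm(p * p), p)
  sig <- crossprod(a) / p
  gam <- function(n) {
    x <- matrix(rnorm(n * p), n) %*% chol(sig)
    ledoit_wolf_gamma(scale(x, center = TRUE, scale = FALSE))
  }
  g_small <- mean(replicate(5, gam(15)))
  g_big <- mean(replicate(5, gam(400)))
  expect_true(g_small >= 0 && g_small <= 1)
  expect_gt(g_small, g_big)
})

test_that("exact-zero scores resolve to IS and are counted", {
  m <- structure(list(weights = c(1, 0), bias = 0, shrinkage_intensity = 0,
                      class_order = c("IS", "MA")), class = "lda_model")
  pred <- predict_lda(m, rbind(c(0, 5), c(1, 0), c(-1, 0)))
  expect_equal(as.character(pred), c("IS", "MA", "IS"))
  expect_equal(attr(pred, "ties"), 1L)
  expect_error(predict_lda(m, matrix(0, 1, 3)), "dimension")
})

test_that("bagging is reproducible, reduces to sLDA under the identity hook, and votes", {
  set.seed(15)
  x <- rbind(matrix(rnorm(60, sd = 0.4), 30, 2),
             sweep(matrix(rnorm(60, sd = 0.4), 30, 2), 2, c(3, 3), "+"))
  fm <- feature_matrix(x, rep(c("IS", "MA"), each = 30))
  # separability oracle: a single linear discriminant classifies perfectly
  expect_equal(mean(predict_lda(fit_slda(fm, 0), fm) == fm$labels), 1)
  e1 <- fit_bagged_rlda(fm, n_learners = 10, seed = 42)
  e2 <- fit_bagged_rlda(fm, n_learners = 10, seed = 42)
  expect_identical(lapply(e1$learners, `[[`, "weights"),
                   lapply(e2$learners, `[[`, "weights"))
  single <- fit_bagged_rlda(fm, n_learners = 1, identity_resample = TRUE)
  ref <- fit_slda(fm, shrinkage = 0.1)
  expect_equal(single$learners[[1]]$weights, ref$weights, tolerance = 1e-12)
  full <- fit_bagged_rlda(fm, n_learners = 50, seed = 0)
  expect_length(full$learners, 50)
  expect_equal(as.character(predict_vote(full, fm)), as.character(fm$labels))
  # identical learners vote like the single learner
  clone <- full
  clone$learners <- rep(list(ref), 50)
  expect_equal(as.character(predict_vote(clone, fm)),
               as.character(predict_lda(ref, fm)))
})

test_that("a 25-25 vote tie is broken by the mean decision score", {
  pos <- structure(list(weights = 1, bias = 0.5, shrinkage_intensity = 0,
                        class_order = c("IS", "MA")), class = "lda_model")
  neg <- structure(list(weights = -1, bias = 0.4, shrinkage_intensity = 0,
                        class_order = c("IS", "MA")), class = "lda_model")
  ens <- structure(list(learners = c(rep(list(pos), 25), rep(list(neg), 25)),
                        n_learners = 50), class = "bagged_ensemble")
  # at x=1: 25 scores +1.5, 25 scores -0.6 -> tie, mean 0.45 > 0 -> MA
  expect_equal(as.character(predict_vote(ens, matrix(1))), "MA")
  # at x=-1: 25 scores -0.5, 25 scores +1.4 -> tie, mean 0.45 > 0 -> MA
  expect_equal(as.character(predict_vote(ens, matrix(-1))), "MA")
  # flip biases so the mean is negative
  ens$learners <- c(rep(list(structure(list(weights = 1, bias = -0.5,
                                            class_order = c("IS", "MA")),
                                       class = "lda_model")), 25),
                    rep(list(structure(list(weights = -1, bias = -0.6,
                                            class_order = c("IS", "MA")),
                                       class = "lda_model")), 25))
  expect_equal(as.character(predict_vote(ens, matrix(0.1))), "IS")
})

test_that("random ensembles on random features predict balanced classes", {
  # average over independently fit ensembles so that the (random) placement
  # of any single decision boundary averages out; the pooled MA fraction then
  # sits inside the 99% binomial band around 0.5
  set.seed(16)
  n_ens <- 20
  n_per <- 500
  hits <- 0
  for (k in seq_len(n_ens)) {
    x <- matrix(rnorm(200), 100, 2)
    fm <- feature_matrix(x, rep(c("IS", "MA"), 50))
    ens <- fit_bagged_rlda(fm, n_learners = 11, seed = k)
    xt <- matrix(rnorm(2 * n_per), n_per, 2)
    hits <- hits + sum(predict_vote(ens, xt) == "MA")
  }
  n_tot <- n_ens * n_per
  half_width <- stats::qnorm(0.995) * sqrt(0.25 / n_tot)
  expect_gt(hits / n_tot, 0.5 - half_width)
  expect_lt(hits / n_tot, 0.5 + half_width)
})

test_that("contract errors: single class, tiny classes, singular covariance", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fit_slda(feature_matrix(x, rep("MA", 10))), "class")
  expect_error(fit_bagged_rlda(feature_matrix(x, c("MA", rep("IS", 9)))), "2 samples")
  xs <- cbind(rep(c(0, 1), each = 5), rep(c(0, 1), each = 5)) # collinear
  expect_error(fit_slda(feature_matrix(xs, rep(c("IS", "MA"), each = 5)),
                        shrinkage = 0), "singular|shrinkage")
})
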