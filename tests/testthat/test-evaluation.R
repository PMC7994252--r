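test_that("LOSO folds have the reference bookkeeping (18 subjects -> 1020/60)", {
  man <- dataset_manifest(sprintf("S%02d", 1:18), trials_per_class = 30)
  folds <- make_loso_folds(man)
  expect_length(folds, 18)
  for (f in folds) {
    expect_equal(f$n_train_samples, 1020L)
    expect_equal(f$n_test_samples, 60L)
    expect_false(f$test_subject %in% f$train_subjects)
    expect_length(f$train_subjects, 17)
  }
  expect_setequal(vapply(folds, `[[`, character(1), "test_subject"), man$subjects)
})

test_that("two subjects give two mutually-training folds; duplicates are rejected", {
  man <- dataset_manifest(c("A", "B"), trials_per_class = 5)
  folds <- make_loso_folds(man)
  expect_length(folds, 2)
  expect_equal(folds[[1]]$train_subjects, "B")
  expect_equal(folds[[2]]$train_subjects, "A")
  expect_error(dataset_manifest(c("A", "A"), 5), "duplicate")
  expect_error(make_loso_folds(dataset_manifest("A", 5)), "2 subjects")
})

test_that("a constant always-MA classifier scores exactly 0.5 on balanced folds", {
  se <- simulate_epochs(quick_sim(n_subjects = 3, trials_per_class = 6))
  always_ma <- list(
    tag = "always_ma",
    fit = function(ep) NULL,
    predict = function(m, ep) factor(rep("MA", dim(ep$data)[1]),
                                     levels = c("IS", "MA"))
  )
  rep <- run_loso(se$epochs, always_ma)
  expect_true(all(rep$per_subject_accuracy == 0.5))
  expect_equal(rep$mean, 0.5)
})

test_that("the leakage audit passes on simulated data and pooled accuracy decomposes", {
  se <- simulate_epochs(quick_sim(n_subjects = 3, trials_per_class = 6))
  rep <- run_loso(se$epochs, "slda", seed = 0)
  expect_true(rep$leakage_audited)
  # equal per-subject trial counts: pooled accuracy equals the mean
  expect_equal(pooled_accuracy(rep), mean(rep$per_subject_accuracy))
  expect_equal(rep$mean, mean(rep$per_subject_accuracy))
  expect_equal(rep$se, rep$sd / sqrt(3))
})

test_that("run_loso aborts when a fold would train on a single class", {
  se <- simulate_epochs(quick_sim(n_subjects = 2, trials_per_class = 6))
  ep <- se$epochs
  keep <- ep$subject_ids == "S01" | ep$labels == "MA"
  bad <- subset_epochs(ep, which(keep))
  expect_error(run_loso(bad, "slda"), "single-class")
})

test_that("pseudo-online bookkeeping: N=12 trains on 24 and tests on 36 trials", {
  se <- simulate_epochs(sim_config(n_subjects = 1, trials_per_class = 30,
                                   n_channels = 4, seed = 2))
  curve <- run_pseudo_online(se$epochs, n_grid = c(12, 28))
  r12 <- curve[curve$n_train_per_class == 12, ]
  expect_equal(r12$n_train, 24L)
  expect_equal(r12$n_test, 36L)
  r28 <- curve[curve$n_train_per_class == 28, ]
  expect_equal(r28$n_test, 4L)
  expect_error(run_pseudo_online(se$epochs, n_grid = 30), "range")
  expect_error(run_pseudo_online(se$epochs, n_grid = 1), "range")
  # bit-reproducibility
  curve2 <- run_pseudo_online(se$epochs, n_grid = c(12, 28))
  expect_identical(curve, curve2)
})

test_that("pseudo-online uses the chronologically first N trials per class", {
  # construct trials whose class pattern flips after the first 2 MA trials:
  # if training uses the chronologically first 2 per class, the learned rule
  # misclassifies every remaining MA trial and accepts every IS trial -> 0.5
  set.seed(33)
  n_tr <- 12
  labs <- rep(c("IS", "MA"), 6)
  x <- array(stats::rnorm(n_tr * 10 * 2, sd = 0.01), c(n_tr, 10, 2))
  ma <- which(labs == "MA")
  x[ma[1:2], , 1] <- x[ma[1:2], , 1] + 1     # early MA: +1
  x[ma[3:6], , 1] <- x[ma[3:6], , 1] - 1     # late MA: -1 (like IS)
  x[labs == "IS", , 1] <- x[labs == "IS", , 1] - 1
  ep <- toy_epoch_set(x, labs, window_s = c(0, 9 / FS))
  curve <- run_pseudo_online(ep, n_grid = 2,
                             opts = list(windows = list(c(0, 9 / FS)),
                                         shrinkage = 0.5))
  expect_equal(curve$n_train, 4L)
  expect_equal(curve$n_test, 8L)
  expect_equal(curve$accuracy, 0.5)
})

test_that("exact Wilcoxon p-values match enumeration oracles and the stats reference", {
  # all-positive differences, n = 6: two-sided p = 2/64
  res <- wilcoxon_signed_rank(1:6 + (1:6), 1:6)
  expect_equal(res$p_value, 0.03125)
  expect_equal(res$statistic, 21)
  # single non-zero pair among many: p = 1 from the n=1 distribution
  a <- rep(0.7, 7); b <- a; b[3] <- 0.65
  expect_equal(wilcoxon_signed_rank(a, b)$p_value, 1.0)
  # anti-symmetric differences: p = 1 by symmetry
  d <- c(0.5, -0.5, 0.3, -0.3, 0.2, -0.2)
  expect_equal(wilcoxon_signed_rank(d, rep(0, 6))$p_value, 1.0)
  # tie-free random pairs agree exactly with the reference implementation
  set.seed(31)
  for (k in 1:5) {
    aa <- stats::runif(10 + k); bb <- stats::runif(10 + k)
    expect_equal(wilcoxon_signed_rank(aa, bb)$p_value,
                 stats::wilcox.test(aa, bb, paired = TRUE, exact = TRUE)$p.value)
  }
  expect_error(wilcoxon_signed_rank(rep(1, 6), rep(1, 6)), "degenerate")
  expect_error(wilcoxon_signed_rank(1:5, 2:6), "6 pairs")
})
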