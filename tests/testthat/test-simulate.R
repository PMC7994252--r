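noise_free <- function(...) {
  sim_config(noise = list(mayer = 0, resp = 0, cardiac = 0, drift = 0, white = 0),
             gain_sdlog = 0, trial_sdlog = 0, spatial_jitter_sd = 0, ...)
}

test_that("a default subject has 60 events, 30 per class, sorted and in range", {
  s <- simulate_subject(sim_config(n_subjects = 1, seed = 5), 1)
  ev <- s$recording$events
  expect_equal(nrow(ev), 60L)
  expect_equal(as.numeric(table(ev$label)), c(30, 30))
  expect_false(is.unsorted(ev$onset_sample))
  expect_true(all(ev$onset_sample >= 1 &
                    ev$onset_sample <= dim(s$recording$hb)[1]))
})

test_that("no noise and no effect produce an identically zero recording", {
  cfg <- noise_free(n_subjects = 1, trials_per_class = 3, n_channels = 2,
                    effect_amplitude = 0, seed = 6)
  s <- simulate_subject(cfg, 1)
  expect_true(all(s$recording$hb == 0))
})

test_that("a noise-free MA trial peaks at the boxcar-HRF convolution oracle", {
  cfg <- noise_free(n_subjects = 1, trials_per_class = 1, n_channels = 2,
                    effect_amplitude = 0.01, spatial_pattern = c(1, 1), seed = 7)
  s <- simulate_subject(cfg, 1)
  # independent oracle: direct discrete convolution of the boxcar with the HRF
  fs <- cfg$sampling_rate_hz
  t <- seq(0, 30, by = 1 / fs)
  hrf <- hrf_double_gamma(t)
  box <- as.numeric(t < 10)
  conv <- numeric(length(t))
  for (i in seq_along(t)) {
    conv[i] <- sum(box[seq_len(i)] * rev(hrf[seq_len(i)])) / fs
  }
  # the template is scaled to unit peak, so the recording peak equals the
  # configured amplitude, and the template shape must match the oracle
  expect_equal(max(s$recording$hb[, 1, 1]), 0.01, tolerance = 1e-9)
  # HbR is anti-correlated at a third of the amplitude
  expect_equal(min(s$recording$hb[, 1, 2]), -0.01 / 3, tolerance = 1e-9)
  # and the response shape matches the oracle template up to scale
  tmpl <- response_template(cfg)
  expect_equal(tmpl, conv / max(conv), tolerance = 1e-9)
})

test_that("simulation is deterministic in (seed, subject) and subjects differ", {
  cfg <- quick_sim(n_subjects = 2, seed = 9)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$recordings[[1]]$hb, b$recordings[[1]]$hb)
  expect_identical(a$recordings[[2]]$hb, b$recordings[[2]]$hb)
  expect_false(identical(a$recordings[[1]]$hb, a$recordings[[2]]$hb))
  c1 <- simulate_dataset(quick_sim(n_subjects = 2, seed = 10))
  expect_false(identical(a$recordings[[1]]$hb, c1$recordings[[1]]$hb))
})

test_that("the default dataset reproduces the reference LOSO bookkeeping", {
  ds <- simulate_dataset(sim_config(n_subjects = 18, trials_per_class = 30,
                                    n_channels = 1, seed = 11))
  folds <- make_loso_folds(ds$manifest)
  expect_length(folds, 18)
  expect_true(all(vapply(folds, `[[`, numeric(1), "n_train_samples") == 1020))
  expect_true(all(vapply(folds, `[[`, numeric(1), "n_test_samples") == 60))
  expect_equal(ds$manifest$source, "synthetic")
})

test_that("subject gains follow the configured log-normal law", {
  cfg <- sim_config(n_subjects = 100, trials_per_class = 2, n_channels = 1,
                    gain_sdlog = 0.35, seed = 12)
  gains <- vapply(1:100, function(i) simulate_subject(cfg, i)$truth$gain,
                  numeric(1))
  ks <- stats::ks.test(gains, "plnorm", meanlog = 0, sdlog = 0.35)
  expect_gt(ks$p.value, 0.01)
})

test_that("the MA-IS mean epoch difference converges to the scaled template", {
  cfg <- sim_config(n_subjects = 1, trials_per_class = 250, n_channels = 1,
                    effect_amplitude = 0.01, spatial_pattern = 1,
                    gain_sdlog = 0, trial_sdlog = 0, spatial_jitter_sd = 0,
                    noise = list(mayer = 0, resp = 0, cardiac = 0, drift = 0,
                                 white = 0.01),
                    seed = 13)
  s <- simulate_subject(cfg, 1)
  ep <- epoch(s$recording)
  ma <- colMeans(ep$data[ep$labels == "MA", , 1])
  is <- colMeans(ep$data[ep$labels == "IS", , 1])
  diffc <- ma - is
  tmpl <- response_template(cfg)[1:201]
  tmpl <- tmpl - mean(tmpl[1]) # baseline-corrected at onset (template starts at 0)
  n <- sum(ep$labels == "MA")
  tol <- 3 * 0.01 * sqrt(2) / sqrt(n) # 3 sd of a mean difference of white noise
  expect_lt(max(abs(diffc - 0.01 * tmpl)), tol + 1e-6)
})

test_that("band-pass preprocessing preserves the epoched response energy", {
  cfg <- noise_free(n_subjects = 1, trials_per_class = 15, n_channels = 1,
                    effect_amplitude = 0.01, spatial_pattern = 1, seed = 3)
  s <- simulate_subject(cfg, 1)
  raw <- epoch(s$recording)
  fil <- epoch(bandpass(s$recording))
  ma <- which(raw$labels == "MA")
  retained <- sum(fil$data[ma, , 1]^2) / sum(raw$data[ma, , 1]^2)
  expect_gt(retained, 0.8)
})

test_that("invalid noise amplitudes are rejected", {
  expect_error(sim_config(noise = list(mayer = -1, resp = 0, cardiac = 0,
                                       drift = 0, white = 0)), ">= 0")
})
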