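# Shared fixtures, all generated in code.

FS <- 40 / 3

# A minimal epoch_set built directly from an array.
toy_epoch_set <- function(data, labels, subject_ids = "S01",
                          window_s = c(0, 15), fs = FS) {
  epoch_set(data, labels, subject_ids,
            spec = list(window_s = window_s, baseline_s = c(-1, 0),
                        sampling_rate_hz = fs))
}

# Epochs whose MA trials carry a smooth temporal bump on the first half of the
# signals; shape (not offset) differences survive per-trial z-scoring.
separable_epochs <- function(n_trials = 80, n_time = 60, n_signals = 8,
                             amplitude = 3, seed = 11) {
  set.seed(seed)
  labels <- rep(c("IS", "MA"), length.out = n_trials)
  x <- array(stats::rnorm(n_trials * n_time * n_signals),
             c(n_trials, n_time, n_signals))
  bump <- sin(seq(0, pi, length.out = n_time))
  for (i in which(labels == "MA")) {
    for (cc in seq_len(max(1, n_signals %/% 2))) {
      x[i, , cc] <- x[i, , cc] + amplitude * bump
    }
  }
  toy_epoch_set(x, labels)
}

# Small, fast simulation configurations.
quick_sim <- function(n_subjects = 3, trials_per_class = 6, seed = 1, ...) {
  sim_config(n_subjects = n_subjects, trials_per_class = trials_per_class,
             n_channels = 4, seed = seed, ...)
}

# Hand-rolled two-class LDA used as an independent oracle (no shrinkage).
oracle_fisher_lda <- function(x, y01) {
  x0 <- x[y01 == 0, , drop = FALSE]
  x1 <- x[y01 == 1, , drop = FALSE]
  mu0 <- colMeans(x0); mu1 <- colMeans(x1)
  s <- (crossprod(sweep(x0, 2, mu0)) + crossprod(sweep(x1, 2, mu1))) /
    (nrow(x) - 2)
  w <- solve(s) %*% (mu1 - mu0)
  b <- -sum(w * (mu0 + mu1)) / 2
  list(w = as.numeric(w), b = b)
}
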