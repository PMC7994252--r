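# Epoch segmentation, baseline correction, normalization, features ------------

#' Epoching specification
#'
#' @param window_s epoch window relative to task onset, seconds; both
#'   endpoints are included, so `[0, 15]` s at 40/3 Hz yields 201 samples.
#' @param baseline_s baseline interval, seconds; samples with
#'   `baseline_s[1] <= t < baseline_s[2]` enter the baseline mean (the onset
#'   sample itself belongs to the epoch, not the baseline).
#' @return a list of class `epoch_spec`.
#' @export
epoch_spec <- function(window_s = c(0, 15), baseline_s = c(-1, 0)) {
  stopifnot(length(window_s) == 2, window_s[2] > window_s[1])
  stopifnot(length(baseline_s) == 2, baseline_s[2] > baseline_s[1])
  if (baseline_s[2] > window_s[1]) {
    stop("baseline interval must precede the epoch window", call. = FALSE)
  }
  structure(list(window_s = as.numeric(window_s), baseline_s = as.numeric(baseline_s)),
            class = "epoch_spec")
}

window_offsets <- function(window_s, fs) {
  # integer sample offsets k with window_s[1] <= k/fs <= window_s[2]
  seq(ceiling(window_s[1] * fs - 1e-9), floor(window_s[2] * fs + 1e-9))
}

baseline_offsets <- function(baseline_s, fs) {
  # half-open [a, b): a <= k/fs < b
  lo <- ceiling(baseline_s[1] * fs - 1e-9)
  hi <- ceiling(baseline_s[2] * fs - 1e-9) - 1
  seq(lo, hi)
}

#' Segment a continuous recording into baseline-corrected epochs
#'
#' Cuts one epoch per event over `spec$window_s` (endpoints inclusive) and
#' subtracts, per channel and chromophore, the temporal mean over the
#' baseline interval. Events too close to a record boundary for a full
#' baseline-plus-window cut are dropped with a warning; the number of dropped
#' events is returned in the `dropped` attribute so that
#' `n_epochs + dropped == n_events` always holds.
#'
#' The epoch tensor flattens channel x chromophore into one axis: columns
#' `1..n_channels` are HbO, columns `n_channels+1..2*n_channels` are HbR
#' (see [epoch_axis_names()]).
#'
#' @param rec an [hb_recording()].
#' @param spec an [epoch_spec()].
#' @return an [epoch_set()] with attribute `dropped` (integer count).
#' @export
epoch <- function(rec, spec = epoch_spec()) {
  if (!inherits(rec, "hb_recording")) stop("epoch expects an hb_recording", call. = FALSE)
  fs <- rec$sampling_rate_hz
  w_off <- window_offsets(spec$window_s, fs)
  b_off <- baseline_offsets(spec$baseline_s, fs)
  d <- dim(rec$hb)
  n_time <- length(w_off)
  n_sig <- d[2] * 2
  onsets <- rec$events$onset_sample
  ok <- onsets + min(b_off) >= 1 & onsets + max(w_off) <= d[1]
  dropped <- sum(!ok)
  if (dropped > 0) {
    warning(sprintf("dropped %d event(s) too close to the record boundary", dropped),
            call. = FALSE)
  }
  keep <- which(ok)
  data <- array(0, dim = c(length(keep), n_time, n_sig))
  # flatten [n_time, ch, 2] -> [n_time, 2*ch] as HbO block then HbR block
  for (i in seq_along(keep)) {
    on <- onsets[keep[i]]
    seg <- rec$hb[on + w_off, , , drop = FALSE]
    base <- rec$hb[on + b_off, , , drop = FALSE]
    bmean <- colMeans(base, dims = 1) # [ch, 2]
    seg <- sweep(seg, c(2, 3), bmean, "-")
    data[i, , ] <- cbind(seg[, , 1], seg[, , 2])
  }
  out <- epoch_set(
    data = data,
    labels = as.character(rec$events$label[keep]),
    subject_ids = rec$subject_id,
    spec = list(window_s = spec$window_s, baseline_s = spec$baseline_s,
                sampling_rate_hz = fs),
    normalized = FALSE,
    signal_names = epoch_axis_names(rec$channel_names)
  )
  attr(out, "dropped") <- dropped
  out
}

#' Z-score epochs over the time axis
#'
#' For every trial and signal (channel x chromophore), subtracts the temporal
#' mean and divides by the population standard deviation (divisor `n`). A
#' signal whose standard deviation is below `eps` is mapped to all zeros
#' rather than NaN. Normalizing an already-normalized epoch set is a contract
#' error, since the operation is meant to be applied exactly once before a
#' network sees the data.
#'
#' @param ep an [epoch_set()].
#' @param eps guard threshold for constant signals.
#' @return the normalized [epoch_set()] with `normalized = TRUE`.
#' @export
zscore_time <- function(ep, eps = 1e-12) {
  if (!inherits(ep, "epoch_set")) stop("zscore_time expects an epoch_set", call. = FALSE)
  if (ep$normalized) stop("epoch set is already z-score normalized", call. = FALSE)
  d <- dim(ep$data)
  xp <- aperm(ep$data, c(2, 1, 3))      # [time, trial, signal]
  dim(xp) <- c(d[2], d[1] * d[3])
  mu <- colMeans(xp)
  xp <- sweep(xp, 2, mu, "-")
  sdv <- sqrt(colMeans(xp^2))
  scale <- ifelse(sdv < eps, 0, 1 / pmax(sdv, eps))
  xp <- sweep(xp, 2, scale, "*")
  dim(xp) <- c(d[2], d[1], d[3])
  ep$data <- aperm(xp, c(2, 1, 3))
  ep$normalized <- TRUE
  ep
}

#' Temporal mean-amplitude features
#'
#' Builds the classical fNIRS feature vector: the temporal mean amplitude of
#' every channel and chromophore within each requested window. With 16
#' channels, 2 chromophores and the default windows 0-5, 5-10 and 10-15 s the
#' feature dimension is 96. Ordering is window-major: all signals of window 1
#' (HbO channels then HbR channels), then window 2, etc. Window endpoints are
#' inclusive.
#'
#' @param ep an [epoch_set()].
#' @param windows_s list of length-2 numeric windows in seconds, relative to
#'   the task onset; must lie inside the epoch window.
#' @return a list of class `feature_matrix` with `values`
#'   (`n_trials x n_features`), `labels`, `subject_ids`, `feature_names`.
#' @export
extract_mean_features <- function(ep, windows_s = list(c(0, 5), c(5, 10), c(10, 15))) {
  if (!inherits(ep, "epoch_set")) {
    stop("extract_mean_features expects an epoch_set", call. = FALSE)
  }
  fs <- ep$spec$sampling_rate_hz
  w_off <- window_offsets(ep$spec$window_s, fs)
  d <- dim(ep$data)
  blocks <- list()
  nms <- character(0)
  for (w in windows_s) {
    stopifnot(length(w) == 2, w[1] < w[2])
    if (w[1] < ep$spec$window_s[1] - 1e-9 || w[2] > ep$spec$window_s[2] + 1e-9) {
      stop("feature window lies outside the epoch window", call. = FALSE)
    }
    sel <- which(w_off / fs >= w[1] - 1e-9 & w_off / fs <= w[2] + 1e-9)
    sub <- ep$data[, sel, , drop = FALSE]
    means <- colMeans(aperm(sub, c(2, 1, 3))) # over time -> [trial*signal]
    dim(means) <- c(d[1], d[3])
    blocks[[length(blocks) + 1]] <- means
    nms <- c(nms, paste0(ep$signal_names, sprintf(".w%g-%g", w[1], w[2])))
  }
  values <- do.call(cbind, blocks)
  colnames(values) <- nms
  if (any(!is.finite(values))) stop("features contain NaN/Inf", call. = FALSE)
  structure(
    list(values = values, labels = ep$labels, subject_ids = ep$subject_ids,
         feature_names = nms),
    class = "feature_matrix"
  )
}
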