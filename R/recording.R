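#' @keywords internal
"_PACKAGE"

# Package-wide conventions ----------------------------------------------------
#
# * Chromophore axis order is always (HbO, HbR).
# * The flattened 32-wide epoch axis is channel-major within chromophore:
#   columns 1..n_channels are HbO ch1..chN, columns n_channels+1..2n are HbR.
# * Class labels are a factor with levels c("IS", "MA"); IS is coded 0 and MA
#   1 wherever a numeric encoding is needed, so a positive LDA score means MA.
# * Event onsets are 1-based sample indices into the continuous recording.

NIRSBCI_WAVELENGTHS <- c(780, 805, 830)
NIRSBCI_CHROMOPHORES <- c("HbO", "HbR")
NIRSBCI_CLASSES <- c("IS", "MA")

#' Default sampling rate of the reference montage
#'
#' The acquisition rate is nominally printed as 13.3 Hz; a \[0, 15\] s epoch
#' that is inclusive of both endpoints and contains exactly 201 samples forces
#' the exact rational rate 40/3 Hz, which is what the package uses.
#'
#' @export
nirsbci_default_fs <- function() 40 / 3

class_factor <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (!all(labels %in% NIRSBCI_CLASSES)) {
    stop("labels must be 'IS' or 'MA'", call. = FALSE)
  }
  factor(labels, levels = NIRSBCI_CLASSES)
}

validate_events <- function(events, n_samples) {
  stopifnot(is.data.frame(events), all(c("onset_sample", "label") %in% names(events)))
  if (nrow(events) > 0) {
    if (any(events$onset_sample < 1 | events$onset_sample > n_samples)) {
      stop("event onsets must lie within [1, n_samples]", call. = FALSE)
    }
    if (is.unsorted(events$onset_sample)) {
      stop("events must be sorted by onset_sample", call. = FALSE)
    }
  }
  events$label <- class_factor(events$label)
  events
}

#' Construct a continuous optical-density recording
#'
#' @param od numeric array `[n_samples, n_channels, 3]` of optical-density
#'   changes at the three wavelengths 780, 805, 830 nm (in that order).
#' @param sampling_rate_hz sampling rate in Hz.
#' @param events data frame with columns `onset_sample` (1-based sample index
#'   of each task onset) and `label` (`"MA"` or `"IS"`), sorted by onset.
#' @param subject_id subject identifier string.
#' @param channel_names optional character vector of channel names.
#' @param wavelengths_nm wavelengths of the third axis, ascending; must be
#'   `c(780, 805, 830)` for the hemoglobin conversion to apply.
#' @return an object of class `od_recording`.
#' @export
od_recording <- function(od, sampling_rate_hz, events, subject_id = "S01",
                         channel_names = NULL,
                         wavelengths_nm = NIRSBCI_WAVELENGTHS) {
  stopifnot(is.array(od), length(dim(od)) == 3)
  if (dim(od)[3] != 3) stop("od must have 3 wavelength planes", call. = FALSE)
  if (!identical(as.numeric(wavelengths_nm), as.numeric(NIRSBCI_WAVELENGTHS))) {
    stop("wavelengths must be (780, 805, 830) nm in ascending order", call. = FALSE)
  }
  stopifnot(sampling_rate_hz > 0)
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(dim(od)[2]))
  }
  stopifnot(length(channel_names) == dim(od)[2])
  events <- validate_events(events, dim(od)[1])
  structure(
    list(
      subject_id = subject_id,
      sampling_rate_hz = sampling_rate_hz,
      wavelengths_nm = as.numeric(wavelengths_nm),
      od = od,
      events = events,
      channel_names = channel_names
    ),
    class = "od_recording"
  )
}

#' Construct a continuous hemoglobin-concentration recording
#'
#' @param hb numeric array `[n_samples, n_channels, 2]`, chromophore order
#'   (HbO, HbR), units mM·cm (concentration change times path length).
#' @inheritParams od_recording
#' @param filter_log list of filter records already applied to `hb`
#'   (append-only; each [bandpass()] call appends one entry).
#' @return an object of class `hb_recording`.
#' @export
hb_recording <- function(hb, sampling_rate_hz, events, subject_id = "S01",
                         channel_names = NULL, filter_log = list()) {
  stopifnot(is.array(hb), length(dim(hb)) == 3)
  if (dim(hb)[3] != 2) stop("hb must have 2 chromophore planes (HbO, HbR)", call. = FALSE)
  stopifnot(sampling_rate_hz > 0)
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(dim(hb)[2]))
  }
  stopifnot(length(channel_names) == dim(hb)[2])
  events <- validate_events(events, dim(hb)[1])
  structure(
    list(
      subject_id = subject_id,
      sampling_rate_hz = sampling_rate_hz,
      hb = hb,
      events = events,
      channel_names = channel_names,
      filter_log = filter_log
    ),
    class = "hb_recording"
  )
}

#' @export
print.od_recording <- function(x, ...) {
  d <- dim(x$od)
  cat(sprintf(
    "<od_recording> subject %s: %d samples x %d channels x 3 wavelengths @ %.4f Hz, %d events\n",
    x$subject_id, d[1], d[2], x$sampling_rate_hz, nrow(x$events)
  ))
  invisible(x)
}

#' @export
print.hb_recording <- function(x, ...) {
  d <- dim(x$hb)
  cat(sprintf(
    "<hb_recording> subject %s: %d samples x %d channels x (HbO, HbR) @ %.4f Hz, %d events, %d filters\n",
    x$subject_id, d[1], d[2], x$sampling_rate_hz, nrow(x$events), length(x$filter_log)
  ))
  invisible(x)
}

#' Column names of the flattened channel-by-chromophore epoch axis
#'
#' @param channel_names character vector of channel names.
#' @return character vector of length `2 * length(channel_names)`: the HbO
#'   block followed by the HbR block.
#' @export
epoch_axis_names <- function(channel_names) {
  c(paste0("HbO.", channel_names), paste0("HbR.", channel_names))
}

#' Construct an epoch set
#'
#' @param data numeric array `[n_trials, n_time, n_signals]` where the third
#'   axis holds HbO channels followed by HbR channels.
#' @param labels class labels, one per trial (`"IS"`/`"MA"`).
#' @param subject_ids subject identifier per trial.
#' @param spec list describing the epoching (window, baseline, sampling rate).
#' @param normalized logical; whether [zscore_time()] has been applied.
#' @param signal_names optional names of the third axis.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, subject_ids, spec, normalized = FALSE,
                      signal_names = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  labels <- class_factor(labels)
  stopifnot(length(labels) == dim(data)[1])
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) == 1) subject_ids <- rep(subject_ids, dim(data)[1])
  stopifnot(length(subject_ids) == dim(data)[1])
  if (is.null(signal_names)) signal_names <- sprintf("sig%03d", seq_len(dim(data)[3]))
  structure(
    list(
      data = data,
      labels = labels,
      subject_ids = subject_ids,
      spec = spec,
      normalized = isTRUE(normalized),
      signal_names = signal_names
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials x %d samples x %d signals (%d subjects)%s\n",
    d[1], d[2], d[3], length(unique(x$subject_ids)),
    if (x$normalized) ", z-scored" else ""
  ))
  print(table(x$labels))
  invisible(x)
}

#' Subset an epoch set by trial index
#'
#' @param ep an `epoch_set`.
#' @param idx integer or logical trial index.
#' @return the subsetted `epoch_set`.
#' @export
subset_epochs <- function(ep, idx) {
  epoch_set(
    data = ep$data[idx, , , drop = FALSE],
    labels = ep$labels[idx],
    subject_ids = ep$subject_ids[idx],
    spec = ep$spec,
    normalized = ep$normalized,
    signal_names = ep$signal_names
  )
}

#' Concatenate epoch sets along the trial axis
#'
#' @param ... `epoch_set` objects with identical time/signal axes.
#' @return a single `epoch_set`.
#' @export
bind_epochs <- function(...) {
  eps <- list(...)
  if (length(eps) == 1 && is.list(eps[[1]]) && !inherits(eps[[1]], "epoch_set")) {
    eps <- eps[[1]]
  }
  stopifnot(length(eps) >= 1)
  d <- dim(eps[[1]]$data)
  for (e in eps) stopifnot(identical(dim(e$data)[2:3], d[2:3]))
  n <- sum(vapply(eps, function(e) dim(e$data)[1], integer(1)))
  out <- array(0, dim = c(n, d[2], d[3]))
  at <- 1
  for (e in eps) {
    k <- dim(e$data)[1]
    if (k > 0) out[at:(at + k - 1), , ] <- e$data
    at <- at + k
  }
  epoch_set(
    data = out,
    labels = unlist(lapply(eps, function(e) as.character(e$labels))),
    subject_ids = unlist(lapply(eps, function(e) e$subject_ids)),
    spec = eps[[1]]$spec,
    normalized = all(vapply(eps, function(e) e$normalized, logical(1))),
    signal_names = eps[[1]]$signal_names
  )
}
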