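# Zero-phase Butterworth band-pass filtering ----------------------------------

#' Band-pass filter specification
#'
#' Defaults follow the standard fNIRS BCI choice: a 6th-order Butterworth
#' band-pass at 0.01-0.09 Hz applied forward and backward (zero phase). The
#' designed band-pass has order `order` (i.e. `order/2` pole pairs per edge);
#' the forward-backward application squares its magnitude response.
#'
#' @param band_hz length-2 numeric, lower and upper pass-band edges in Hz.
#' @param order even integer, order of the designed band-pass filter.
#' @return a list of class `filter_spec`.
#' @export
filter_spec <- function(band_hz = c(0.01, 0.09), order = 6) {
  if (length(band_hz) != 2 || band_hz[1] <= 0 || band_hz[1] >= band_hz[2]) {
    stop("band_hz must satisfy 0 < low < high", call. = FALSE)
  }
  if (order %% 2 != 0 || order < 2) {
    stop("band-pass order must be a positive even integer", call. = FALSE)
  }
  structure(list(band_hz = as.numeric(band_hz), order = as.integer(order),
                 family = "butterworth", phase = "zero"),
            class = "filter_spec")
}

butter_design <- function(spec, fs) {
  ny <- fs / 2
  if (spec$band_hz[2] >= ny) {
    stop("upper band edge must be below the Nyquist frequency", call. = FALSE)
  }
  # signal::butter doubles the order for a band-pass design
  signal::butter(spec$order / 2, spec$band_hz / ny, type = "pass")
}

#' Theoretical forward-backward gain of the band-pass filter
#'
#' Magnitude-squared response of the designed Butterworth band-pass (the
#' forward-backward application squares the one-pass magnitude), used as an
#' oracle for pass-band and stop-band behaviour.
#'
#' @param spec a [filter_spec()].
#' @param fs sampling rate in Hz.
#' @param freq_hz frequencies at which to evaluate the gain.
#' @return numeric vector of linear amplitude gains.
#' @export
bandpass_gain <- function(spec, fs, freq_hz) {
  bf <- butter_design(spec, fs)
  w <- 2 * pi * freq_hz / fs
  h <- vapply(w, function(wi) {
    z <- exp(-1i * wi * seq_along(bf$b) + 1i * wi)
    num <- sum(bf$b * z)
    den <- sum(bf$a * z)
    Mod(num / den)
  }, numeric(1))
  h^2
}

#' Zero-phase band-pass filter a hemoglobin recording
#'
#' Each channel and chromophore is filtered independently with a Butterworth
#' band-pass applied forward and backward ([signal::filtfilt()]), giving zero
#' phase distortion; the DC component is removed because it lies below the
#' lower band edge. The applied filter is appended to the recording's
#' `filter_log` (re-filtering is recorded again: the log reflects what was
#' actually applied).
#'
#' @param rec an [hb_recording()].
#' @param spec a [filter_spec()]; defaults to 0.01-0.09 Hz, order 6.
#' @return the filtered [hb_recording()].
#' @export
bandpass <- function(rec, spec = filter_spec()) {
  if (!inherits(rec, "hb_recording")) {
    stop("bandpass expects an hb_recording", call. = FALSE)
  }
  fs <- rec$sampling_rate_hz
  bf <- butter_design(spec, fs)
  d <- dim(rec$hb)
  # settling length of the slow edge: ~3 periods of the lower band edge
  min_len <- ceiling(3 * fs / spec$band_hz[1])
  if (d[1] < min_len) {
    stop(sprintf(
      "recording too short for stable filtering (%d samples < %d); pad or record longer",
      d[1], min_len
    ), call. = FALSE)
  }
  out <- rec$hb
  for (ch in seq_len(d[2])) {
    for (cr in 1:2) {
      x <- rec$hb[, ch, cr]
      # remove the mean first: the offset lies outside the pass band anyway
      # and stresses the narrow-band IIR numerically
      out[, ch, cr] <- signal::filtfilt(bf, x - mean(x))
    }
  }
  rec$hb <- out
  rec$filter_log <- c(rec$filter_log, list(list(
    family = spec$family,
    band_hz = spec$band_hz,
    order = spec$order,
    phase = spec$phase,
    applied = "forward-backward"
  )))
  rec
}
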