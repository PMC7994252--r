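# SNIRF interchange -------------------------------------------------------------
#
# SNIRF is an HDF5 container; the package bridges to the Python h5py library
# through a bundled helper script, exchanging the time series as raw float64.

find_python <- function() {
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop("SNIRF support requires a 'python' executable with h5py on the PATH",
       call. = FALSE)
}

snirf_helper <- function() {
  path <- system.file("python", "snirf_io.py", package = "nirsbci")
  if (!nzchar(path)) stop("bundled SNIRF helper not found", call. = FALSE)
  path
}

run_snirf_helper <- function(args) {
  out <- suppressWarnings(system2(find_python(), c(shQuote(snirf_helper()), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("SNIRF helper failed: ", paste(out, collapse = "\n"), call. = FALSE)
  }
  invisible(out)
}

#' Write a recording to a SNIRF file
#'
#' Optical-density recordings are stored as processed `dOD` measurements with
#' wavelength indices; hemoglobin recordings as processed `HbO`/`HbR`
#' measurements. Events become one stimulus group per class with onsets in
#' seconds. The round trip through [read_snirf()] is lossless to float64
#' precision.
#'
#' @param rec an [od_recording()] or [hb_recording()].
#' @param path output file path.
#' @param task_duration_s stimulus duration stored with each event.
#' @return `path`, invisibly.
#' @export
write_snirf <- function(rec, path, task_duration_s = 10) {
  if (inherits(rec, "od_recording")) {
    arr <- rec$od
    kind <- "od"
    wl <- rec$wavelengths_nm
  } else if (inherits(rec, "hb_recording")) {
    arr <- rec$hb
    kind <- "hb"
    wl <- NIRSBCI_WAVELENGTHS
  } else {
    stop("write_snirf expects an od_recording or hb_recording", call. = FALSE)
  }
  d <- dim(arr)
  fs <- rec$sampling_rate_hz
  events <- lapply(seq_len(nrow(rec$events)), function(i) {
    list(onset_s = (rec$events$onset_sample[i] - 1) / fs,
         duration_s = task_duration_s,
         label = as.character(rec$events$label[i]))
  })
  meta <- list(
    kind = kind, n_samples = d[1], n_channels = d[2], n_planes = d[3],
    sampling_rate_hz = fs, subject_id = rec$subject_id,
    wavelengths_nm = wl, events = events
  )
  meta_f <- tempfile(fileext = ".json")
  data_f <- tempfile(fileext = ".raw")
  on.exit(unlink(c(meta_f, data_f)))
  jsonlite::write_json(meta, meta_f, auto_unbox = TRUE, digits = NA)
  con <- file(data_f, "wb")
  writeBin(as.vector(arr), con, size = 8, endian = "little")
  close(con)
  run_snirf_helper(c("write", shQuote(meta_f), shQuote(data_f), shQuote(path)))
  invisible(path)
}

#' Read a SNIRF file
#'
#' Returns an [od_recording()] for optical-density or raw-intensity files
#' (raw intensities `I` are converted to optical-density change as
#' `-log10(I / mean(I))` per channel) and an [hb_recording()] for processed
#' HbO/HbR files.
#'
#' @param path a SNIRF file.
#' @return an [od_recording()] or [hb_recording()].
#' @export
read_snirf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta_f <- tempfile(fileext = ".json")
  data_f <- tempfile(fileext = ".raw")
  on.exit(unlink(c(meta_f, data_f)))
  run_snirf_helper(c("read", shQuote(path), shQuote(meta_f), shQuote(data_f)))
  meta <- jsonlite::read_json(meta_f, simplifyVector = TRUE)
  n <- meta$n_samples * meta$n_channels * meta$n_planes
  con <- file(data_f, "rb")
  vals <- readBin(con, what = "double", n = n, size = 8, endian = "little")
  close(con)
  arr <- array(vals, dim = c(meta$n_samples, meta$n_channels, meta$n_planes))
  fs <- meta$sampling_rate_hz
  ev <- meta$events
  events <- if (is.data.frame(ev) && nrow(ev) > 0) {
    data.frame(onset_sample = as.integer(round(ev$onset_s * fs)) + 1L,
               label = ev$label)
  } else {
    data.frame(onset_sample = integer(0), label = character(0))
  }
  if (meta$kind == "hb") {
    hb_recording(arr, fs, events, subject_id = meta$subject_id)
  } else {
    if (meta$kind == "intensity") {
      for (ch in seq_len(meta$n_channels)) {
        for (pl in seq_len(meta$n_planes)) {
          i0 <- mean(arr[, ch, pl])
          arr[, ch, pl] <- -log10(arr[, ch, pl] / i0)
        }
      }
    }
    od_recording(arr, fs, events, subject_id = meta$subject_id)
  }
}
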