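# Internal on-disk dataset format -----------------------------------------------
#
# A dataset directory holds one RDS archive per subject (arrays + metadata)
# and a JSON manifest:
#   { "subjects": [...], "trials_per_class": 30, "classes": ["IS","MA"],
#     "source": "synthetic", "files": {"S01": "S01.rds", ...} }

#' Construct a dataset manifest
#'
#' @param subjects character vector of subject ids (unique).
#' @param trials_per_class trials per class per subject.
#' @param classes class labels, default `c("IS", "MA")`.
#' @param source one of `"synthetic"`, `"snirf"`, `"figshare"`.
#' @param files named character vector mapping subject id to file name.
#' @return a list of class `dataset_manifest`.
#' @export
dataset_manifest <- function(subjects, trials_per_class,
                             classes = NIRSBCI_CLASSES,
                             source = "synthetic", files = NULL) {
  subjects <- as.character(subjects)
  if (anyDuplicated(subjects)) stop("duplicate subject ids in manifest", call. = FALSE)
  structure(list(
    subjects = subjects,
    trials_per_class = as.integer(trials_per_class),
    classes = as.character(classes),
    source = source,
    files = files
  ), class = "dataset_manifest")
}

#' Write a dataset (recordings + manifest) to a directory
#'
#' @param recordings list of [hb_recording()] objects.
#' @param dir output directory (created if needed).
#' @param trials_per_class trials per class (for the manifest).
#' @param source manifest source tag.
#' @return the [dataset_manifest()], invisibly.
#' @export
write_dataset <- function(recordings, dir, trials_per_class, source = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subjects <- vapply(recordings, function(r) r$subject_id, character(1))
  files <- paste0(subjects, ".rds")
  names(files) <- subjects
  for (i in seq_along(recordings)) {
    saveRDS(recordings[[i]], file.path(dir, files[i]))
  }
  man <- dataset_manifest(subjects, trials_per_class, source = source, files = files)
  jsonlite::write_json(
    list(subjects = man$subjects, trials_per_class = man$trials_per_class,
         classes = man$classes, source = man$source, files = as.list(files)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(man)
}

#' Read a dataset manifest from a directory
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return a [dataset_manifest()].
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", dir, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  dataset_manifest(j$subjects, j$trials_per_class, j$classes, j$source,
                   unlist(j$files))
}

#' Load all subjects of a dataset
#'
#' @param dir dataset directory.
#' @param manifest optional [dataset_manifest()]; read from `dir` if missing.
#' @return list of [hb_recording()] in manifest order.
#' @export
load_dataset <- function(dir, manifest = NULL) {
  if (is.null(manifest)) manifest <- read_manifest(dir)
  lapply(manifest$subjects, function(s) {
    f <- file.path(dir, manifest$files[[s]])
    if (!file.exists(f)) {
      stop(sprintf("missing data file for subject '%s' (%s)", s, f), call. = FALSE)
    }
    readRDS(f)
  })
}
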