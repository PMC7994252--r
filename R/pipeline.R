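# Run configuration and end-to-end pipeline -------------------------------------

#' Build a run configuration
#'
#' A fully serializable description of one experiment: simulate (or load) a
#' dataset, preprocess it, and evaluate a classifier with LOSO or the
#' pseudo-online learning curve. Defaults reproduce the reference settings
#' (0.01-0.09 Hz order-6 band-pass, \[0,15\] s epochs with (-1,0) s baseline,
#' 0-5/5-10/10-15 s feature windows, Adamax 0.0005 with seed 0).
#'
#' @param command `"loso"` or `"curve"`.
#' @param model classifier name (`"slda"`, `"bagging"`, `"cnn"`, `"eegnet"`).
#' @param sim list of [sim_config()] overrides (e.g. `n_subjects`, `seed`).
#' @param input_dir optional dataset directory (internal format) used instead
#'   of simulation.
#' @param band_hz,filter_order band-pass settings.
#' @param window_s,baseline_s epoch settings.
#' @param n_grid pseudo-online grid (curve command).
#' @param seed classifier seed.
#' @param out_dir output directory for report artifacts (NULL: don't write).
#' @return a list of class `run_config`.
#' @export
run_config <- function(command = c("loso", "curve"), model = "slda",
                       sim = list(), input_dir = NULL,
                       band_hz = c(0.01, 0.09), filter_order = 6,
                       window_s = c(0, 15), baseline_s = c(-1, 0),
                       n_grid = seq(2, 28, by = 2), seed = 0,
                       out_dir = NULL) {
  command <- match.arg(command)
  if (!(band_hz[1] > 0 && band_hz[1] < band_hz[2])) {
    stop("invalid field band_hz: need 0 < low < high", call. = FALSE)
  }
  if (baseline_s[2] > window_s[1]) {
    stop("invalid field baseline_s: baseline must precede the epoch window",
         call. = FALSE)
  }
  structure(list(
    command = command, model = model, sim = sim, input_dir = input_dir,
    band_hz = band_hz, filter_order = filter_order,
    window_s = window_s, baseline_s = baseline_s,
    n_grid = n_grid, seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg[setdiff(names(cfg), "out_dir")]), tmp,
                       auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

#' Execute a run configuration
#'
#' Simulates (or loads) the dataset, preprocesses it, runs the requested
#' evaluation and, if `out_dir` is set, writes `report.json` and
#' `report.csv` together with a provenance record (config hash, package
#' version, seeds).
#'
#' @param cfg a [run_config()].
#' @return the evaluation result (an `evaluation_report` or learning-curve
#'   data frame) with a `provenance` attribute.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  fspec <- filter_spec(cfg$band_hz, cfg$filter_order)
  espec <- epoch_spec(cfg$window_s, cfg$baseline_s)
  if (!is.null(cfg$input_dir)) {
    recs <- load_dataset(cfg$input_dir)
  } else {
    scfg <- do.call(sim_config, cfg$sim)
    recs <- simulate_dataset(scfg)$recordings
  }
  eps <- bind_epochs(lapply(recs, preprocess_recording, fspec = fspec, espec = espec))
  result <- if (cfg$command == "loso") {
    run_loso(eps, model = cfg$model, seed = cfg$seed)
  } else {
    run_pseudo_online(eps, n_grid = cfg$n_grid)
  }
  prov <- list(
    config_hash = config_hash(cfg),
    package_version = as.character(utils::packageVersion("nirsbci")),
    seed = cfg$seed,
    command = cfg$command,
    model = cfg$model
  )
  attr(result, "provenance") <- prov
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (inherits(result, "evaluation_report")) {
      jsonlite::write_json(
        list(provenance = prov, model = result$model_tag,
             mean_accuracy = result$mean, sd_accuracy = result$sd,
             per_subject_accuracy = as.list(result$per_subject_accuracy)),
        file.path(cfg$out_dir, "report.json"), auto_unbox = TRUE, digits = NA
      )
      utils::write.csv(
        data.frame(subject = names(result$per_subject_accuracy),
                   accuracy = as.numeric(result$per_subject_accuracy)),
        file.path(cfg$out_dir, "report.csv"), row.names = FALSE
      )
    } else {
      jsonlite::write_json(
        list(provenance = prov,
             curve = attr(result, "summary")),
        file.path(cfg$out_dir, "report.json"), auto_unbox = TRUE, digits = NA
      )
      utils::write.csv(result, file.path(cfg$out_dir, "report.csv"),
                       row.names = FALSE)
    }
  }
  result
}
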