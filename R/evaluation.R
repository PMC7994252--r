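# LOSO cross-validation and pseudo-online simulation -----------------------------

#' Leave-one-subject-out folds
#'
#' One fold per subject: the subject's trials are the test set, everyone
#' else's the training set. With 18 subjects and 30 trials per class this
#' gives 18 folds of 1,020 training and 60 test samples.
#'
#' @param manifest a [dataset_manifest()].
#' @return list of folds, each with `test_subject`, `train_subjects`,
#'   `n_train_samples`, `n_test_samples`.
#' @export
make_loso_folds <- function(manifest) {
  subjects <- manifest$subjects
  if (anyDuplicated(subjects)) stop("duplicate subject ids", call. = FALSE)
  if (length(subjects) < 2) stop("LOSO needs at least 2 subjects", call. = FALSE)
  per_subject <- manifest$trials_per_class * length(manifest$classes)
  lapply(subjects, function(s) {
    list(
      test_subject = s,
      train_subjects = setdiff(subjects, s),
      n_train_samples = per_subject * (length(subjects) - 1L),
      n_test_samples = per_subject
    )
  })
}

trial_fingerprints <- function(ep) {
  d <- dim(ep$data)
  flat <- ep$data
  dim(flat) <- c(d[1], d[2] * d[3])
  w <- sin(seq_len(d[2] * d[3]))
  sprintf("%.10e|%.10e", rowSums(abs(flat)), as.numeric(flat %*% w))
}

# Classifier adapters: each exposes fit(train_ep) and predict(fitted, test_ep).
classifier_adapter <- function(model, opts, seed) {
  if (is.list(model) && !is.null(model$fit) && !is.null(model$predict)) {
    return(c(model, list(tag = model$tag %||% "custom")))
  }
  model <- match.arg(model, c("slda", "bagging", "cnn", "eegnet"))
  windows <- opts$windows %||% list(c(0, 5), c(5, 10), c(10, 15))
  tspec <- opts$train_spec %||% train_spec(rng_seed = seed)
  switch(model,
    slda = list(
      tag = "slda",
      fit = function(ep) fit_slda(extract_mean_features(ep, windows),
                                  shrinkage = opts$shrinkage %||% "analytic"),
      predict = function(m, ep) predict_lda(m, extract_mean_features(ep, windows))
    ),
    bagging = list(
      tag = "bagging",
      fit = function(ep) fit_bagged_rlda(extract_mean_features(ep, windows),
                                         n_learners = opts$n_learners %||% 50,
                                         resample_fraction = opts$resample_fraction %||% 1.0,
                                         gamma = opts$gamma %||% 0.1,
                                         seed = seed),
      predict = function(m, ep) predict_vote(m, extract_mean_features(ep, windows))
    ),
    cnn = list(
      tag = "cnn",
      fit = function(ep) {
        d <- dim(ep$data)
        cfg <- opts$cnn_config %||% cnn_config(input_time = d[2], input_channels = d[3])
        train_network(build_proposed_cnn(cfg, seed = tspec$rng_seed),
                      zscore_time(ep), tspec)
      },
      predict = function(m, ep) predict_network(m, zscore_time(ep))
    ),
    eegnet = list(
      tag = "eegnet",
      fit = function(ep) {
        d <- dim(ep$data)
        cfg <- opts$eegnet_config %||% eegnet_config(input_rows = d[3], input_time = d[2])
        train_network(build_eegnet(cfg, seed = tspec$rng_seed),
                      zscore_time(ep), tspec)
      },
      predict = function(m, ep) predict_network(m, zscore_time(ep))
    )
  )
}

#' Run leave-one-subject-out cross-validation
#'
#' For each fold the classifier is fit on the training subjects only (any
#' normalization and validation split happen inside the fold on training
#' data), then the held-out subject's trials are classified. A trial-level
#' fingerprint audit asserts that no test trial entered the training set.
#'
#' @param ep an [epoch_set()] spanning all subjects (not normalized; network
#'   classifiers z-score internally, per trial).
#' @param model `"slda"`, `"bagging"`, `"cnn"`, `"eegnet"`, or a custom list
#'   with `fit(train_ep)` and `predict(fitted, test_ep)`.
#' @param opts list of classifier options (`windows`, `shrinkage`,
#'   `n_learners`, `gamma`, `train_spec`, `cnn_config`, `eegnet_config`).
#' @param seed integer seed for classifier randomness.
#' @param check_leakage run the fingerprint audit (default TRUE).
#' @return an `evaluation_report`: per-subject accuracies, mean, sd, standard
#'   error, fold definitions, seed and model tag.
#' @export
run_loso <- function(ep, model = "slda", opts = list(), seed = 0,
                     check_leakage = TRUE) {
  stopifnot(inherits(ep, "epoch_set"))
  subjects <- unique(ep$subject_ids)
  if (length(subjects) < 2) stop("LOSO needs at least 2 subjects", call. = FALSE)
  ad <- classifier_adapter(model, opts, seed)
  fps <- if (check_leakage) trial_fingerprints(ep) else NULL
  audit_ok <- is.null(fps) || !any(duplicated(fps))
  acc <- stats::setNames(numeric(length(subjects)), subjects)
  folds <- list()
  predictions <- list()
  for (s in subjects) {
    te <- which(ep$subject_ids == s)
    tr <- which(ep$subject_ids != s)
    if (check_leakage) {
      if (length(intersect(tr, te)) > 0) stop("leakage: shared trial indices", call. = FALSE)
      if (audit_ok && length(intersect(fps[tr], fps[te])) > 0) {
        stop("leakage audit failed for fold ", s, call. = FALSE)
      }
    }
    train_ep <- subset_epochs(ep, tr)
    if (nlevels(droplevels(train_ep$labels)) < 2) {
      stop("fold ", s, " has single-class training data", call. = FALSE)
    }
    fitted <- ad$fit(train_ep)
    pred <- ad$predict(fitted, subset_epochs(ep, te))
    truth <- ep$labels[te]
    acc[s] <- mean(pred == truth)
    predictions[[s]] <- data.frame(subject = s, truth = truth, pred = pred)
    folds[[s]] <- list(test_subject = s, train_subjects = setdiff(subjects, s),
                       n_train_samples = length(tr), n_test_samples = length(te))
  }
  structure(list(
    model_tag = ad$tag,
    per_subject_accuracy = acc,
    mean = mean(acc), sd = stats::sd(acc),
    se = stats::sd(acc) / sqrt(length(acc)),
    folds = folds,
    predictions = do.call(rbind, predictions),
    rng_seed = seed,
    leakage_audited = isTRUE(check_leakage) && audit_ok
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s: mean accuracy %.2f%% +/- %.2f%% (sd) over %d subjects\n",
              x$model_tag, 100 * x$mean, 100 * x$sd, length(x$per_subject_accuracy)))
  invisible(x)
}

#' Pooled accuracy of an evaluation report
#'
#' @param report an `evaluation_report`.
#' @return accuracy over all pooled test trials.
#' @export
pooled_accuracy <- function(report) {
  mean(report$predictions$pred == report$predictions$truth)
}

#' Pseudo-online subject-dependent learning curve
#'
#' For each subject and each `N` in `n_grid`, trains a shrinkage LDA on the
#' chronologically first `N` trials of each class and tests on the remaining
#' `30 - N` (more generally `trials_per_class - N`) trials of that subject
#' only.
#'
#' @param ep an [epoch_set()] with trials in acquisition order per subject.
#' @param n_grid integer vector of training-set sizes per class.
#' @param opts classifier options (`windows`, `shrinkage`).
#' @return data frame with one row per (subject, N): `subject`, `n_train_per_class`,
#'   `n_train`, `n_test`, `accuracy`; plus a `summary` attribute aggregated by N.
#' @export
run_pseudo_online <- function(ep, n_grid = seq(2, 28, by = 2), opts = list()) {
  stopifnot(inherits(ep, "epoch_set"))
  windows <- opts$windows %||% list(c(0, 5), c(5, 10), c(10, 15))
  shrink <- opts$shrinkage %||% "analytic"
  subjects <- unique(ep$subject_ids)
  rows <- list()
  for (s in subjects) {
    idx <- which(ep$subject_ids == s)
    labs <- ep$labels[idx]
    per_class <- min(table(labs))
    for (nn in n_grid) {
      if (nn < 2 || nn > per_class - 1) {
        stop(sprintf("N=%d outside the valid range [2, %d]", nn, per_class - 1),
             call. = FALSE)
      }
      tr <- integer(0); te <- integer(0)
      for (cl in NIRSBCI_CLASSES) {
        ci <- idx[labs == cl]
        tr <- c(tr, ci[seq_len(nn)])
        te <- c(te, ci[-seq_len(nn)])
      }
      f_tr <- extract_mean_features(subset_epochs(ep, sort(tr)), windows)
      f_te <- extract_mean_features(subset_epochs(ep, sort(te)), windows)
      m <- fit_slda(f_tr, shrinkage = shrink)
      accuracy <- mean(predict_lda(m, f_te) == f_te$labels)
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, n_train_per_class = nn,
        n_train = length(tr), n_test = length(te), accuracy = accuracy
      )
    }
  }
  out <- do.call(rbind, rows)
  agg <- stats::aggregate(accuracy ~ n_train_per_class, data = out, FUN = mean)
  attr(out, "summary") <- agg
  out
}
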