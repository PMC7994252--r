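# Shrinkage LDA and bagged regularized LDA ------------------------------------

#' Build a feature matrix object from raw values
#'
#' @param values numeric matrix `n_trials x n_features`.
#' @param labels class labels (`"IS"`/`"MA"`).
#' @param subject_ids optional subject identifier per trial.
#' @return a `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, subject_ids = "S01") {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("features contain NaN/Inf", call. = FALSE)
  labels <- class_factor(labels)
  stopifnot(nrow(values) == length(labels))
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) == 1) subject_ids <- rep(subject_ids, nrow(values))
  nms <- colnames(values)
  if (is.null(nms)) nms <- sprintf("f%03d", seq_len(ncol(values)))
  structure(list(values = values, labels = labels, subject_ids = subject_ids,
                 feature_names = nms),
            class = "feature_matrix")
}

pooled_class_stats <- function(x, y) {
  # y: factor with levels (IS, MA); returns means and pooled covariance
  i0 <- which(y == "IS")
  i1 <- which(y == "MA")
  if (length(i0) < 2 || length(i1) < 2) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  mu0 <- colMeans(x[i0, , drop = FALSE])
  mu1 <- colMeans(x[i1, , drop = FALSE])
  xc <- x
  xc[i0, ] <- sweep(x[i0, , drop = FALSE], 2, mu0, "-")
  xc[i1, ] <- sweep(x[i1, , drop = FALSE], 2, mu1, "-")
  n <- nrow(x)
  sigma <- crossprod(xc) / (n - 2)
  list(mu0 = mu0, mu1 = mu1, sigma = sigma, xc = xc, n = n)
}

#' Analytic shrinkage intensity (Ledoit-Wolf, identity-scaled target)
#'
#' Estimates the optimal convex weight for shrinking a sample covariance
#' toward `nu * I`, where `nu` is the average of the diagonal, following the
#' Ledoit-Wolf quadratic-loss argument. Computed from the class-centered
#' samples so it applies to the pooled within-class covariance.
#'
#' @param xc matrix of class-centered observations (rows).
#' @return shrinkage intensity clipped to `[0, 1]`.
#' @export
ledoit_wolf_gamma <- function(xc) {
  n <- nrow(xc)
  p <- ncol(xc)
  s <- crossprod(xc) / n
  mnu <- sum(diag(s)) / p
  d2 <- sum((s - diag(mnu, p))^2) / p
  if (d2 < .Machine$double.eps) return(0)
  b2sum <- 0
  x2 <- xc^2
  # sum_k ||x_k x_k' - S||_F^2 = sum_k (x_k'x_k)^2 - 2 tr(S x_k x_k') + n tr(S^2)
  sq_norms <- rowSums(x2)
  tr_s2 <- sum(s^2)
  xs <- xc %*% s
  b2sum <- sum(sq_norms^2) - 2 * sum(xs * xc) + n * tr_s2
  b2 <- min(b2sum / (n^2 * p), d2)
  max(0, min(1, b2 / d2))
}

#' Fit a (shrinkage-)regularized linear discriminant
#'
#' Classical two-class LDA with the pooled within-class covariance shrunk
#' toward a scaled identity: `S_g = (1 - g) S + g nu I` with
#' `nu = mean(diag(S))`. The discriminant is `w = solve(S_g, mu_MA - mu_IS)`
#' with bias placing the boundary midway between the class means; a positive
#' score means MA. With `shrinkage = "analytic"` the intensity is the
#' Ledoit-Wolf estimate ([ledoit_wolf_gamma()]).
#'
#' @param features a `feature_matrix` (or [extract_mean_features()] output).
#' @param shrinkage `"analytic"` or a fixed value in `[0, 1]`.
#' @return a list of class `lda_model` with `weights`, `bias`,
#'   `shrinkage_intensity`, `class_order = c("IS", "MA")`.
#' @export
fit_slda <- function(features, shrinkage = "analytic") {
  x <- features$values
  y <- features$labels
  if (nlevels(droplevels(y)) < 2) stop("training data contain a single class", call. = FALSE)
  st <- pooled_class_stats(x, y)
  gam <- if (identical(shrinkage, "analytic")) {
    ledoit_wolf_gamma(st$xc)
  } else {
    g <- as.numeric(shrinkage)
    stopifnot(g >= 0, g <= 1)
    g
  }
  p <- ncol(x)
  nu <- sum(diag(st$sigma)) / p
  sig <- (1 - gam) * st$sigma + diag(gam * nu, p)
  w <- tryCatch(
    solve(sig, st$mu1 - st$mu0),
    error = function(e) stop("covariance is singular; use shrinkage > 0", call. = FALSE)
  )
  b <- -sum(w * (st$mu0 + st$mu1)) / 2
  structure(
    list(weights = as.numeric(w), bias = as.numeric(b),
         shrinkage_intensity = gam, class_order = NIRSBCI_CLASSES,
         feature_names = features$feature_names),
    class = "lda_model"
  )
}

#' Decision scores of a linear discriminant
#'
#' @param model an `lda_model`.
#' @param features a `feature_matrix` or plain matrix.
#' @return numeric vector `w'x + b` per trial (positive = MA).
#' @export
lda_score <- function(model, features) {
  x <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  if (ncol(x) != length(model$weights)) {
    stop("feature dimension does not match the model", call. = FALSE)
  }
  as.numeric(x %*% model$weights + model$bias)
}

#' Predict class labels with a linear discriminant
#'
#' Positive scores map to MA, negative to IS; an exact zero resolves to IS
#' and is counted in the `ties` attribute.
#'
#' @inheritParams lda_score
#' @return factor of labels with attribute `ties`.
#' @export
predict_lda <- function(model, features) {
  s <- lda_score(model, features)
  lab <- factor(ifelse(s > 0, "MA", "IS"), levels = NIRSBCI_CLASSES)
  attr(lab, "ties") <- sum(s == 0)
  lab
}

#' Fit a bagged ensemble of regularized LDAs
#'
#' Bootstrap aggregation: each learner is a fixed-shrinkage LDA
#' (`gamma = 0.1` by default) fit on a with-replacement resample of the
#' training set of size `resample_fraction * n`. A resample that misses a
#' class is redrawn (count recorded in `redraws`). The reference
#' configuration is 50 learners, 100% resampling, gamma 0.1.
#'
#' @param features a `feature_matrix`.
#' @param n_learners number of weak learners.
#' @param resample_fraction fraction of the training-set size per resample.
#' @param gamma fixed shrinkage intensity of each learner.
#' @param seed integer RNG seed making the resamples reproducible.
#' @param identity_resample if TRUE (test hook) every learner sees the full
#'   training set without resampling, so `n_learners = 1` reduces to
#'   [fit_slda()] with fixed gamma.
#' @return a list of class `bagged_ensemble`.
#' @export
fit_bagged_rlda <- function(features, n_learners = 50, resample_fraction = 1.0,
                            gamma = 0.1, seed = 0, identity_resample = FALSE) {
  x <- features$values
  y <- features$labels
  if (min(table(y)) < 2) stop("need at least 2 samples per class", call. = FALSE)
  n <- nrow(x)
  m <- max(1L, round(resample_fraction * n))
  rng <- local_rng(seed)
  learners <- vector("list", n_learners)
  redraws <- 0L
  for (k in seq_len(n_learners)) {
    if (identity_resample) {
      idx <- seq_len(n)
    } else {
      repeat {
        idx <- rng$sample_int(n, m, replace = TRUE)
        if (length(unique(y[idx])) == 2) break
        redraws <- redraws + 1L
      }
    }
    fm <- feature_matrix(x[idx, , drop = FALSE], y[idx])
    learners[[k]] <- fit_slda(fm, shrinkage = gamma)
  }
  structure(
    list(learners = learners, n_learners = n_learners,
         resample_fraction = resample_fraction, gamma = gamma,
         rng_seed = seed, redraws = redraws,
         vote_rule = "majority; ties by mean decision score"),
    class = "bagged_ensemble"
  )
}

#' Majority-vote prediction of a bagged LDA ensemble
#'
#' Each learner votes with its label; the majority wins. An exact tie (even
#' learner counts) is broken by the sign of the mean decision score across
#' learners (positive = MA, non-positive = IS).
#'
#' @param ens a `bagged_ensemble`.
#' @param features a `feature_matrix` or matrix.
#' @return factor of predicted labels.
#' @export
predict_vote <- function(ens, features) {
  scores <- vapply(ens$learners, function(m) lda_score(m, features),
                   numeric(nrow(if (inherits(features, "feature_matrix")) features$values else features)))
  scores <- matrix(scores, ncol = length(ens$learners))
  votes_ma <- rowSums(scores > 0)
  half <- length(ens$learners) / 2
  mean_score <- rowMeans(scores)
  lab <- ifelse(votes_ma > half, "MA",
                ifelse(votes_ma < half, "IS",
                       ifelse(mean_score > 0, "MA", "IS")))
  factor(lab, levels = NIRSBCI_CLASSES)
}

# Small self-contained RNG wrapper so that model fitting does not disturb the
# caller's RNG stream and is reproducible from an integer seed.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    st
  }
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    expr
  }
  list(
    sample_int = function(n, size, replace = FALSE) with_state(sample.int(n, size, replace = replace)),
    runif = function(n) with_state(stats::runif(n)),
    rnorm = function(n, sd = 1) with_state(stats::rnorm(n, sd = sd))
  )
}
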