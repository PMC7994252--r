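# Shared network trainer --------------------------------------------------------

#' Training specification for the networks
#'
#' Defaults are the reference configuration: Adamax with learning rate 0.0005
#' and legacy per-update decay 5e-8 (`lr_t = lr / (1 + decay * t)`), batch
#' size 100, a stratified random 10% validation split, early stopping on
#' validation loss with patience 20 and best-weight restoration, categorical
#' cross-entropy loss, RNG seed 0.
#'
#' @param learning_rate Adamax learning rate.
#' @param lr_decay per-update learning-rate decay.
#' @param batch_size minibatch size; a training set smaller than this is
#'   trained as one smaller batch.
#' @param validation_fraction fraction of the training data held out for
#'   early stopping.
#' @param patience consecutive epochs without validation-loss improvement
#'   before stopping.
#' @param max_epochs hard cap on training epochs.
#' @param rng_seed seed controlling the split, shuffling and dropout.
#' @return a list of class `train_spec`.
#' @export
train_spec <- function(learning_rate = 5e-4, lr_decay = 5e-8, batch_size = 100,
                       validation_fraction = 0.10, patience = 20,
                       max_epochs = 500, rng_seed = 0) {
  structure(list(
    optimizer = "adamax", learning_rate = learning_rate, lr_decay = lr_decay,
    batch_size = as.integer(batch_size),
    validation_fraction = validation_fraction,
    patience = as.integer(patience), max_epochs = as.integer(max_epochs),
    loss = "categorical_crossentropy", rng_seed = as.integer(rng_seed)
  ), class = "train_spec")
}

model_forward <- function(model, x, training = FALSE) {
  switch(model$kind,
    cnn = cnn_forward(model, x, training),
    eegnet = eegnet_forward(model, x, training),
    stop("unknown model kind: ", model$kind, call. = FALSE)
  )
}

model_backward <- function(model, cache, dlogits) {
  switch(model$kind,
    cnn = cnn_backward(model, cache, dlogits),
    eegnet = eegnet_backward(model, cache, dlogits)
  )
}

# Stratified validation indices: total size round(vf * n), every class
# represented, per-class allocation by largest remainder.
stratified_val_split <- function(labels, vf) {
  n <- length(labels)
  total <- round(vf * n)
  classes <- levels(labels)
  total <- max(total, length(classes))
  quota <- vf * as.numeric(table(labels)[classes])
  base <- pmax(floor(quota), 1)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- quota - floor(quota)
    add <- order(frac, decreasing = TRUE)
    i <- 1
    while (rem > 0) {
      base[add[(i - 1) %% length(base) + 1]] <- base[add[(i - 1) %% length(base) + 1]] + 1
      rem <- rem - 1; i <- i + 1
    }
  } else if (rem < 0) {
    drop_from <- order(base, decreasing = TRUE)
    i <- 1
    while (rem < 0) {
      j <- drop_from[(i - 1) %% length(base) + 1]
      if (base[j] > 1) { base[j] <- base[j] - 1; rem <- rem + 1 }
      i <- i + 1
    }
  }
  val <- integer(0)
  for (ci in seq_along(classes)) {
    pool <- which(labels == classes[ci])
    val <- c(val, sample(pool, base[ci]))
  }
  sort(val)
}

eval_loss <- function(model, x, y01, batch = 200) {
  n <- dim(x)[1]
  tot <- 0
  for (ix in split(seq_len(n), ceiling(seq_len(n) / batch))) {
    fw <- model_forward(model, x[ix, , , drop = FALSE], training = FALSE)
    sc <- softmax_ce(fw$logits, y01[ix])
    tot <- tot + sc$loss * length(ix)
  }
  tot / n
}

#' Train a network on a normalized epoch set
#'
#' Draws a stratified random validation split, minimizes the categorical
#' cross-entropy with Adamax, and stops when the validation loss has not
#' improved for `spec$patience` consecutive epochs, restoring the weights of
#' the best validation epoch. All randomness (split, shuffling, dropout)
#' derives from `spec$rng_seed`, so identical calls give identical results.
#'
#' @param model an untrained `nirsbci_model` from [build_proposed_cnn()] or
#'   [build_eegnet()].
#' @param ep a z-scored [epoch_set()] (`normalized` must be TRUE).
#' @param spec a [train_spec()].
#' @return the trained model with a `log` element (per-epoch train and
#'   validation losses, best/stop epoch, validation indices).
#' @export
train_network <- function(model, ep, spec = train_spec()) {
  if (!inherits(ep, "epoch_set")) stop("train_network expects an epoch_set", call. = FALSE)
  if (!ep$normalized) {
    stop("epoch set must be z-score normalized before training", call. = FALSE)
  }
  if (nlevels(droplevels(ep$labels)) < 2) {
    stop("training data contain a single class", call. = FALSE)
  }
  set.seed(spec$rng_seed)
  n <- dim(ep$data)[1]
  y01 <- as.integer(ep$labels == "MA")
  val_idx <- stratified_val_split(ep$labels, spec$validation_fraction)
  tr_idx <- setdiff(seq_len(n), val_idx)
  xval <- ep$data[val_idx, , , drop = FALSE]
  yval <- y01[val_idx]
  opt <- adamax_init(model$params)
  best <- list(loss = Inf, params = model$params, state = model$state, epoch = 0L)
  waits <- 0L
  log <- data.frame(epoch = integer(0), train_loss = numeric(0), val_loss = numeric(0))
  small_batch_logged <- length(tr_idx) < spec$batch_size
  for (epn in seq_len(spec$max_epochs)) {
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / spec$batch_size))
    tl <- 0
    for (ix in batches) {
      fw <- model_forward(model, ep$data[ix, , , drop = FALSE], training = TRUE)
      model <- fw$model # batch-norm running stats
      sc <- softmax_ce(fw$logits, y01[ix])
      tl <- tl + sc$loss * length(ix)
      grads <- model_backward(model, fw$cache, sc$dlogits)
      upd <- adamax_step(model$params, grads, opt,
                         lr = spec$learning_rate, decay = spec$lr_decay)
      model$params <- upd$params
      opt <- upd$opt
      if (model$kind == "eegnet") model$params <- eegnet_maxnorm(model$params)
    }
    vl <- eval_loss(model, xval, yval)
    log <- rbind(log, data.frame(epoch = epn, train_loss = tl / length(tr_idx),
                                 val_loss = vl))
    if (vl < best$loss) {
      best <- list(loss = vl, params = model$params, state = model$state, epoch = epn)
      waits <- 0L
    } else {
      waits <- waits + 1L
      if (waits >= spec$patience) break
    }
  }
  model$params <- best$params
  model$state <- best$state
  model$trained <- TRUE
  model$log <- list(
    history = log,
    stop_epoch = nrow(log),
    best_epoch = best$epoch,
    best_val_loss = best$loss,
    val_indices = val_idx,
    small_batch = small_batch_logged,
    spec = spec
  )
  model
}

#' Class probabilities of a trained network
#'
#' Inference pass (dropout disabled, batch-norm running statistics); rows sum
#' to one and repeated calls are identical.
#'
#' @param model a trained `nirsbci_model`.
#' @param ep a z-scored [epoch_set()].
#' @return matrix `n_trials x 2` with columns `IS`, `MA`.
#' @export
predict_proba <- function(model, ep) {
  if (!inherits(ep, "epoch_set")) stop("predict_proba expects an epoch_set", call. = FALSE)
  if (!ep$normalized) {
    stop("epoch set must be z-score normalized before prediction", call. = FALSE)
  }
  n <- dim(ep$data)[1]
  out <- matrix(0, n, 2, dimnames = list(NULL, NIRSBCI_CLASSES))
  for (ix in split(seq_len(n), ceiling(seq_len(n) / 200))) {
    fw <- model_forward(model, ep$data[ix, , , drop = FALSE], training = FALSE)
    out[ix, ] <- softmax(fw$logits)
  }
  out
}

#' Predicted class labels of a trained network
#'
#' @inheritParams predict_proba
#' @return factor of `"IS"`/`"MA"` labels.
#' @export
predict_network <- function(model, ep) {
  p <- predict_proba(model, ep)
  factor(ifelse(p[, "MA"] > p[, "IS"], "MA", "IS"), levels = NIRSBCI_CLASSES)
}
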