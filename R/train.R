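#' Source-cohort training configuration
#'
#' One column of the training recipe: epoch budget, minibatch size,
#' augmentation probabilities, Adam learning rate and early-stopping
#' patience. The defaults are the source-model recipe (100 epochs, batch
#' 52, rotation probability 0.5, no flips, lr 1e-4, patience 15, binary
#' cross-entropy loss). "Improvement" for the patience counter means a
#' strictly lower validation loss than the best seen so far; training stops
#' once `early_stop_patience` consecutive epochs fail to improve, and the
#' returned checkpoint is always the best (lowest validation loss) epoch,
#' not the last one. The last incomplete minibatch of an epoch is kept.
#'
#' @param epochs maximum number of epochs (>= 1).
#' @param batch_size minibatch size.
#' @param rotate_prob,flip_prob,max_rotate_deg augmentation settings.
#' @param dropout head dropout probability (overrides the model config's
#'   during training).
#' @param lr Adam learning rate (> 0); remaining Adam constants are the
#'   conventional beta1 0.9, beta2 0.999, eps 1e-8.
#' @param early_stop_patience epochs without improvement before stopping
#'   (>= 1).
#' @param seed integer seed governing shuffling, augmentation, dropout and
#'   (via derivation) weight initialization.
#' @return an object of class `train_spec`.
#' @export
train_spec <- function(epochs = 100, batch_size = 52, rotate_prob = 0.5,
                       flip_prob = 0, max_rotate_deg = 15, dropout = 0.5,
                       lr = 1e-4, early_stop_patience = 15, seed = 1) {
  stop_if_not(lr > 0, "train_spec: lr must be > 0")
  stop_if_not(epochs >= 1, "train_spec: epochs must be >= 1")
  stop_if_not(early_stop_patience >= 1,
              "train_spec: early_stop_patience must be >= 1")
  stop_if_not(batch_size >= 1, "train_spec: batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 rotate_prob = rotate_prob, flip_prob = flip_prob,
                 max_rotate_deg = max_rotate_deg, dropout = dropout,
                 lr = lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "train_spec")
}

# ---- early stopping ---------------------------------------------------------

# Patience-based early stopping as a small state machine, so the rule is
# testable in isolation: "improvement" means a strictly lower validation
# loss than the best so far (no minimum delta); after `patience`
# consecutive non-improving epochs training stops, and the kept snapshot
# is always the best epoch's.
early_stop_init <- function(patience) {
  list(patience = as.integer(patience), best_loss = Inf,
       best_epoch = NA_integer_, best_payload = NULL, bad = 0L,
       stop = FALSE)
}

early_stop_update <- function(state, epoch, val_loss, payload_fn = NULL) {
  if (val_loss < state$best_loss) {
    state$best_loss <- val_loss
    state$best_epoch <- as.integer(epoch)
    if (!is.null(payload_fn)) state$best_payload <- payload_fn()
    state$bad <- 0L
  } else {
    state$bad <- state$bad + 1L
    if (state$bad >= state$patience) state$stop <- TRUE
  }
  state
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(ly) {
    fields <- switch(ly$type, conv = , linear = c("W", "b"),
                     bn3d = , bn1d = c("gamma", "beta"), NULL)
    if (is.null(fields)) return(NULL)
    setNames(lapply(fields, function(f) ly[[f]] * 0), fields)
  })
}

# One Adam update over the per-layer grads structure; returns updated
# layers and state. `t` is the 1-based step counter.
adam_update <- function(layers, grads, m, v, spec, t) {
  b1 <- spec$beta1; b2 <- spec$beta2
  corr1 <- 1 - b1^t
  corr2 <- 1 - b2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (f in names(g)) {
      m[[i]][[f]] <- b1 * m[[i]][[f]] + (1 - b1) * g[[f]]
      v[[i]][[f]] <- b2 * v[[i]][[f]] + (1 - b2) * g[[f]]^2
      step <- spec$lr * (m[[i]][[f]] / corr1) /
        (sqrt(v[[i]][[f]] / corr2) + spec$eps)
      layers[[i]][[f]] <- layers[[i]][[f]] - step
    }
  }
  list(layers = layers, m = m, v = v)
}

bce_loss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Single optimization step on a batch; returns model, adam state, loss.
train_step <- function(model, x, y, m, v, spec, t) {
  fw <- model_forward(model, x, training = TRUE, keep_cache = TRUE)
  model <- fw$model
  loss <- bce_loss(fw$prob, y)
  dlogit <- (fw$prob - y) / length(y)   # d BCE / d logit through the sigmoid
  grads <- model_backward(model, fw$caches, dlogit)
  upd <- adam_update(model$layers, grads, m, v, spec, t)
  model$layers <- upd$layers
  list(model = model, m = upd$m, v = upd$v, loss = loss,
       acc = mean((fw$prob >= 0.5) == y))
}

sample_ids <- function(samples) vapply(samples, `[[`, "", "participant_id")
sample_labels <- function(samples)
  vapply(samples, `[[`, integer(1), "label")

#' Train the source model with hold-out validation and early stopping
#'
#' Runs minibatch Adam optimization of binary cross-entropy with per-epoch
#' shuffling and stochastic augmentation (rotation, and flips if the spec
#' enables them), tracks validation loss after every epoch, stops once the
#' validation loss has not improved for `early_stop_patience` epochs, and
#' returns the model frozen at its best (lowest validation loss) epoch.
#' Samples are expected already preprocessed (resized and per-volume
#' normalized). Two runs with identical inputs and spec produce identical
#' epoch records.
#'
#' @param train,val disjoint lists of [volume_sample()] (validation must be
#'   non-empty).
#' @param spec a [train_spec()].
#' @param config a [cnn_config()] matching the sample dimensions.
#' @param init_seed seed for weight initialization; defaults to a stream
#'   derived from `spec$seed`.
#' @return a list of class `source_fit` with `checkpoint` (the best-epoch
#'   checkpoint including running statistics), `history` (one row
#'   per epoch: `epoch, train_loss, train_accuracy, val_loss,
#'   val_accuracy`), and `stopped_early`.
#' @export
train_source <- function(train, val, spec, config,
                         init_seed = derive_seed(spec$seed, "init")) {
  stop_if_not(inherits(spec, "train_spec"), "train_source: expected a train_spec")
  stop_if_not(length(val) > 0,
              "train_source: validation set must not be empty")
  overlap <- intersect(sample_ids(train), sample_ids(val))
  stop_if_not(length(overlap) == 0,
              "train_source: train/val sets overlap: %s",
              paste(overlap, collapse = ", "))
  model <- build_model(config, init_seed)
  for (i in seq_along(model$layers))
    if (model$layers[[i]]$type == "dropout")
      model$layers[[i]]$p <- spec$dropout
  tf <- transform_spec(resize_to = config$input_size,
                       rotate_prob = spec$rotate_prob,
                       flip_prob = spec$flip_prob,
                       max_rotate_deg = spec$max_rotate_deg)
  y_train <- sample_labels(train)
  y_val <- sample_labels(val)
  train_x <- lapply(train, to_xyzc)
  x_val <- batch_xyzc(lapply(val, to_xyzc))
  m <- adam_init(model$layers)
  v <- adam_init(model$layers)
  history <- data.frame()
  es <- early_stop_init(spec$early_stop_patience)
  t_step <- 0L
  stopped_early <- FALSE
  set.seed(derive_seed(spec$seed, "train"))
  for (epoch in seq_len(spec$epochs)) {
    ord <- sample(length(train))
    ep_loss <- 0; ep_acc <- 0; ep_n <- 0
    starts <- seq(1, length(ord), by = spec$batch_size)
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + spec$batch_size - 1,
                                length(ord))]
      xb <- augment_batch_xyzc(train_x[idx], tf)
      yb <- y_train[idx]
      t_step <- t_step + 1L
      st <- train_step(model, xb, yb, m, v, spec, t_step)
      if (!is.finite(st$loss))
        stop(sprintf("train_source: non-finite loss at epoch %d, batch %d",
                     epoch, bi), call. = FALSE)
      model <- st$model; m <- st$m; v <- st$v
      ep_loss <- ep_loss + st$loss * length(idx)
      ep_acc <- ep_acc + st$acc * length(idx)
      ep_n <- ep_n + length(idx)
    }
    ev <- model_forward(model, x_val, training = FALSE)
    val_loss <- bce_loss(ev$prob, y_val)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / ep_n,
      train_accuracy = ep_acc / ep_n, val_loss = val_loss,
      val_accuracy = mean((ev$prob >= 0.5) == y_val)))
    es <- early_stop_update(es, epoch, val_loss,
                            payload_fn = function() get_weights(model))
    if (es$stop) {
      stopped_early <- TRUE
      break
    }
  }
  ck <- new_checkpoint(config, es$best_payload, epoch = es$best_epoch,
                       val_loss = es$best_loss,
                       provenance = list(
                         seed = spec$seed, init_seed = init_seed,
                         train_ids = sample_ids(train),
                         val_ids = sample_ids(val),
                         spec = unclass(spec)))
  structure(list(checkpoint = ck, history = history,
                 stopped_early = stopped_early),
            class = "source_fit")
}

#' @export
print.source_fit <- function(x, ...) {
  cat(sprintf("<source_fit  %d epochs%s, best epoch %d (val_loss %.4f)>\n",
              nrow(x$history),
              if (x$stopped_early) " (early stop)" else "",
              x$checkpoint$epoch, x$checkpoint$val_loss))
  invisible(x)
}

#' Evaluate a frozen checkpoint on a held-out test set
#'
#' Refuses to score any sample whose id appears in the checkpoint's
#' recorded training or validation ids (a data-leakage hard failure), then
#' runs an eval-mode forward pass at threshold 0.5 and returns the derived
#' metrics.
#'
#' @param checkpoint a `cnn_checkpoint` from [train_source()].
#' @param test non-empty list of preprocessed [volume_sample()].
#' @return a [compute_metrics()] report (with the confusion matrix in
#'   `$confusion`).
#' @export
evaluate_holdout <- function(checkpoint, test) {
  stop_if_not(length(test) > 0, "evaluate_holdout: empty test set")
  ids <- sample_ids(test)
  seen <- c(checkpoint$provenance$train_ids, checkpoint$provenance$val_ids)
  leak <- intersect(ids, seen)
  if (length(leak))
    stop(sprintf("evaluate_holdout: data leakage — test ids also used in training: %s",
                 paste(leak, collapse = ", ")), call. = FALSE)
  model <- restore_model(checkpoint)
  prob <- predict(model, test)
  compute_metrics(confusion_from_predictions(sample_labels(test), prob))
}
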