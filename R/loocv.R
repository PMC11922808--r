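#' Fine-tuning configuration for the leave-one-out protocol
#'
#' The target-cohort recipe: full-batch fine-tuning for a fixed number of
#' epochs with rotation and flip augmentation, a small Adam learning rate,
#' and deliberately **no early stopping** — with a single held-out sample
#' per fold there is no validation signal to stop on, so the spec type has
#' no patience field by construction. The defaults are the transfer recipe
#' (300 epochs, batch 63, rotation and flip probability 0.7, lr 1e-5).
#' `batch_size` is clamped to the fold training size `n - 1` at run time.
#'
#' @param epochs fine-tuning epochs per fold (0 permitted, used by weight
#'   restoration probes).
#' @param batch_size minibatch size before clamping.
#' @param rotate_prob,flip_prob,max_rotate_deg augmentation settings.
#' @param dropout head dropout probability during fine-tuning.
#' @param lr Adam learning rate (> 0).
#' @param seed integer seed; each fold derives its own sub-seed from it and
#'   the held-out participant id, so folds are reproducible in isolation
#'   and independent of execution order.
#' @param mode `"transfer"` (start every fold from the source checkpoint)
#'   or `"reference"` (fresh seeded initialization per fold; the matched
#'   no-transfer arm).
#' @return an object of class `transfer_spec`.
#' @export
transfer_spec <- function(epochs = 300, batch_size = 63, rotate_prob = 0.7,
                          flip_prob = 0.7, max_rotate_deg = 15,
                          dropout = 0.5, lr = 1e-5, seed = 1,
                          mode = c("transfer", "reference")) {
  mode <- match.arg(mode)
  stop_if_not(lr > 0, "transfer_spec: lr must be > 0")
  stop_if_not(epochs >= 0, "transfer_spec: epochs must be >= 0")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 rotate_prob = rotate_prob, flip_prob = flip_prob,
                 max_rotate_deg = max_rotate_deg, dropout = dropout,
                 lr = lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                 seed = as.integer(seed), mode = mode),
            class = "transfer_spec")
}

#' Leave-one-out cross-validated fine-tuning
#'
#' The core protocol: for every participant in the target cohort, (a)
#' initialize the model weights — in transfer mode an exact copy of the
#' source checkpoint, in reference mode a fresh seeded initialization —
#' with **all** parameters trainable; (b) fine-tune on the remaining
#' `n - 1` participants for `spec$epochs` epochs with rotation and flip
#' augmentation redrawn every epoch; (c) predict the held-out participant
#' with an eval-mode forward pass (running batch-norm statistics, dropout
#' off). The weights are discarded and re-initialized for every fold, so no
#' state can cross fold boundaries; this is enforced structurally and can
#' be audited with [leakage_audit()].
#'
#' @param cohort the target cohort: a `synthetic_cohort` or a list of
#'   preprocessed [volume_sample()] objects.
#' @param checkpoint a `cnn_checkpoint` (required for transfer mode; in
#'   reference mode only its config is used, if `config` is not given).
#' @param spec a [transfer_spec()].
#' @param config a [cnn_config()]; defaults to the checkpoint's.
#' @param keep_fold_weights if `TRUE`, the starting weights of every fold
#'   are kept in the result (used by restoration probes).
#' @param fold_order optional permutation of fold execution order; results
#'   are identical for any order.
#' @return an object of class `loocv_result`: `folds` (one row per
#'   participant: `held_out_id, true_label, predicted_probability,
#'   predicted_label, fold_index, fold_seed, init_checksum`), `confusion`,
#'   `metrics`, and `provenance` (mode, spec, source checksum, per-fold
#'   training ids, normalization scope).
#' @export
run_loocv <- function(cohort, checkpoint = NULL, spec = transfer_spec(),
                      config = NULL, keep_fold_weights = FALSE,
                      fold_order = NULL) {
  samples <- if (inherits(cohort, "synthetic_cohort")) cohort$samples
             else cohort
  stop_if_not(is.list(samples) && length(samples) >= 2,
              "run_loocv: need at least 2 samples")
  stop_if_not(all(vapply(samples, inherits, TRUE, "volume_sample")),
              "run_loocv: cohort must contain volume_sample objects")
  stop_if_not(inherits(spec, "transfer_spec"),
              "run_loocv: expected a transfer_spec")
  n <- length(samples)
  ids <- sample_ids(samples)
  labels <- sample_labels(samples)
  stop_if_not(!anyDuplicated(ids), "run_loocv: duplicate participant ids")
  if (spec$mode == "transfer")
    stop_if_not(inherits(checkpoint, "cnn_checkpoint"),
                "run_loocv: transfer mode requires a source checkpoint")
  config <- config %||% checkpoint$config
  stop_if_not(inherits(config, "cnn_config"),
              "run_loocv: no cnn_config available")
  d <- dim(samples[[1]]$data)
  stop_if_not(d[1] == config$in_channels &&
                all(d[2:4] == config$input_size),
              "run_loocv: cohort volumes are %s but the model expects %d x %d^3 (resize/normalize first)",
              paste(d, collapse = "x"), config$in_channels,
              config$input_size)
  batch_size <- min(spec$batch_size, n - 1L)
  tf <- transform_spec(resize_to = config$input_size,
                       rotate_prob = spec$rotate_prob,
                       flip_prob = spec$flip_prob,
                       max_rotate_deg = spec$max_rotate_deg)
  source_weights <- if (!is.null(checkpoint)) checkpoint$weights else NULL
  source_checksum <- if (!is.null(source_weights))
    weight_checksum(source_weights) else NA_real_
  fold_order <- fold_order %||% seq_len(n)
  stop_if_not(setequal(fold_order, seq_len(n)),
              "run_loocv: fold_order must be a permutation of 1..%d", n)
  xyzc <- lapply(samples, to_xyzc)

  folds <- vector("list", n)
  train_ids <- vector("list", n)
  fold_weights <- if (keep_fold_weights) vector("list", n) else NULL
  for (i in fold_order) {
    fold_seed <- derive_seed(spec$seed, "fold", ids[i])
    model <- if (spec$mode == "transfer") {
      set_weights(build_model(config, init_seed = 0), source_weights)
    } else {
      build_model(config, init_seed = derive_seed(fold_seed, "init"))
    }
    for (li in seq_along(model$layers))
      if (model$layers[[li]]$type == "dropout")
        model$layers[[li]]$p <- spec$dropout
    init_w <- get_weights(model)
    if (keep_fold_weights) fold_weights[[i]] <- init_w
    tr_x <- xyzc[-i]
    train_ids[[i]] <- ids[-i]
    y_tr <- labels[-i]
    set.seed(fold_seed)
    if (spec$epochs > 0) {
      m <- adam_init(model$layers)
      v <- adam_init(model$layers)
      t_step <- 0L
      for (epoch in seq_len(spec$epochs)) {
        ord <- sample(length(tr_x))
        starts <- seq(1, length(ord), by = batch_size)
        for (bi in seq_along(starts)) {
          idx <- ord[starts[bi]:min(starts[bi] + batch_size - 1,
                                    length(ord))]
          xb <- augment_batch_xyzc(tr_x[idx], tf)
          t_step <- t_step + 1L
          st <- train_step(model, xb, y_tr[idx], m, v, spec, t_step)
          if (!is.finite(st$loss))
            stop(sprintf("run_loocv: non-finite loss in fold %d (epoch %d)",
                         i, epoch), call. = FALSE)
          model <- st$model; m <- st$m; v <- st$v
        }
      }
    }
    prob <- model_forward(model, batch_xyzc(xyzc[i]),
                          training = FALSE)$prob
    folds[[i]] <- data.frame(
      held_out_id = ids[i], true_label = labels[i],
      predicted_probability = prob,
      predicted_label = as.integer(prob >= 0.5),
      fold_index = i, fold_seed = fold_seed,
      init_checksum = weight_checksum(init_w),
      stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, folds)
  agg <- aggregate_folds(folds)
  structure(list(folds = folds, confusion = agg$confusion,
                 metrics = agg$metrics,
                 provenance = list(
                   mode = spec$mode, spec = unclass(spec),
                   source_checkpoint_checksum = source_checksum,
                   source_checkpoint_epoch =
                     if (!is.null(checkpoint)) checkpoint$epoch else NA,
                   train_ids = setNames(train_ids, ids),
                   normalization = "per_volume",
                   batch_size_used = batch_size),
                 fold_weights = fold_weights),
            class = "loocv_result")
}

#' Pool fold results into a confusion matrix and metrics
#'
#' Aggregation pools the held-out predictions of all folds into a single
#' confusion matrix (rather than averaging per-fold accuracies) and derives
#' the metric suite from the pooled counts.
#'
#' @param folds the `folds` data frame of a [run_loocv()] result (or the
#'   result itself).
#' @return list with `confusion` ([confusion_matrix()]) and `metrics`
#'   ([compute_metrics()] report).
#' @export
aggregate_folds <- function(folds) {
  if (inherits(folds, "loocv_result")) folds <- folds$folds
  stop_if_not(is.data.frame(folds) && nrow(folds) > 0,
              "aggregate_folds: empty fold results")
  dup <- folds$held_out_id[duplicated(folds$held_out_id)]
  if (length(dup))
    stop(sprintf("aggregate_folds: protocol violation — duplicate held-out ids: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  cm <- confusion_from_predictions(folds$true_label,
                                   folds$predicted_probability)
  list(confusion = cm, metrics = compute_metrics(cm))
}

#' Audit a leave-one-out run for data leakage
#'
#' Verifies, from the run's recorded provenance, that (1) every held-out
#' participant is absent from that fold's training ids, (2) the per-fold
#' starting-weight checksums match the protocol arm (transfer folds start
#' bitwise from the source checkpoint; reference folds must not), and
#' (3) intensity normalization was per-volume, so no cohort-level statistic
#' crossed a fold boundary. Violations are returned, not thrown — the
#' report is the output.
#'
#' @param loocv_result a [run_loocv()] result.
#' @param cohort optional cohort the run was computed on (used to check
#'   fold coverage).
#' @return an object of class `leakage_audit` with `violations`
#'   (character vector, empty for a compliant run) and `passed`.
#' @export
leakage_audit <- function(loocv_result, cohort = NULL) {
  stop_if_not(inherits(loocv_result, "loocv_result"),
              "leakage_audit: expected a loocv_result")
  v <- character(0)
  folds <- loocv_result$folds
  prov <- loocv_result$provenance
  dup <- unique(folds$held_out_id[duplicated(folds$held_out_id)])
  if (length(dup))
    v <- c(v, sprintf("duplicate held-out id(s): %s",
                      paste(dup, collapse = ", ")))
  for (i in seq_len(nrow(folds))) {
    id <- folds$held_out_id[i]
    tids <- prov$train_ids[[id]]
    if (!is.null(tids) && id %in% tids)
      v <- c(v, sprintf("fold %d: held-out id %s present in its training set",
                        folds$fold_index[i], id))
  }
  if (identical(prov$mode, "transfer") &&
      is.finite(prov$source_checkpoint_checksum)) {
    bad <- folds$init_checksum != prov$source_checkpoint_checksum
    if (any(bad))
      v <- c(v, sprintf("transfer mode: fold(s) %s did not start from the source checkpoint",
                        paste(folds$fold_index[bad], collapse = ", ")))
  }
  if (identical(prov$mode, "reference") &&
      is.finite(prov$source_checkpoint_checksum)) {
    bad <- folds$init_checksum == prov$source_checkpoint_checksum
    if (any(bad))
      v <- c(v, sprintf("reference mode: fold(s) %s started from the source checkpoint",
                        paste(folds$fold_index[bad], collapse = ", ")))
  }
  if (!identical(prov$normalization, "per_volume"))
    v <- c(v, sprintf("normalization scope is '%s'; cohort-level statistics leak across folds",
                      prov$normalization))
  if (!is.null(cohort)) {
    cohort_ids <- if (inherits(cohort, "synthetic_cohort"))
      cohort$labels$participant_id else sample_ids(cohort)
    if (!setequal(cohort_ids, folds$held_out_id))
      v <- c(v, "fold held-out ids do not cover the cohort exactly")
  }
  structure(list(violations = v, passed = length(v) == 0),
            class = "leakage_audit")
}

#' @export
print.leakage_audit <- function(x, ...) {
  if (x$passed) {
    cat("Leakage audit: PASSED (no violations)\n")
  } else {
    cat("Leakage audit: FAILED\n")
    cat(paste0("  - ", x$violations, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result  %s arm, %d folds>\n", x$provenance$mode,
              nrow(x$folds)))
  print(x$metrics)
  invisible(x)
}

#' @export
summary.loocv_result <- function(object, ...) {
  print(object)
  print(object$confusion)
  invisible(object)
}
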