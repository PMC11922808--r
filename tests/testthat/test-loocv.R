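make_micro_cohort <- function(n_per_group = 3, seed = 23, effect = 2) {
  spec <- synthetic_spec(grid_size = 12, n_channels = 1,
                         n_components_per_channel = 2,
                         n_per_group = n_per_group, effect_size = effect,
                         noise_sd = 0.2, seed = seed)
  generate_cohort(spec, make_component_atlas(spec), 1)
}

test_that("the zero-epoch probe restores the source weights bitwise in every fold", {
  cfg <- micro_cnn_config()
  source_model <- build_model(cfg, init_seed = 31)
  ck <- fmritransfer:::new_checkpoint(cfg, get_weights(source_model))
  cohort <- make_micro_cohort(n_per_group = 8)
  samp <- preprocess_for(cohort, cfg)
  spec <- transfer_spec(epochs = 0, seed = 1, mode = "transfer")
  res <- run_loocv(samp, ck, spec, keep_fold_weights = TRUE)

  expect_equal(nrow(res$folds), 16)
  expect_true(all(lengths(res$provenance$train_ids) == 15))
  expect_setequal(res$folds$held_out_id,
                  fmritransfer:::sample_ids(samp))
  for (fw in res$fold_weights)
    expect_identical(fw, ck$weights)
  expect_true(all(res$folds$init_checksum ==
                    fmritransfer:::weight_checksum(ck$weights)))
  expect_true(leakage_audit(res, samp)$passed)
  expect_equal(res$provenance$batch_size_used, 15L)
})

test_that("fold results are invariant to fold execution order", {
  cfg <- micro_cnn_config()
  ck <- fmritransfer:::new_checkpoint(cfg,
                                      get_weights(build_model(cfg, 31)))
  cohort <- make_micro_cohort(n_per_group = 3)
  samp <- preprocess_for(cohort, cfg)
  spec <- transfer_spec(epochs = 2, lr = 1e-3, seed = 7,
                        mode = "transfer")
  r1 <- run_loocv(samp, ck, spec)
  r2 <- run_loocv(samp, ck, spec, fold_order = rev(seq_along(samp)))
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$metrics$accuracy, r2$metrics$accuracy)

  # and the reference arm re-initializes per fold with distinct seeds
  specr <- transfer_spec(epochs = 0, seed = 7, mode = "reference")
  rr <- run_loocv(samp, spec = specr, config = cfg,
                  keep_fold_weights = TRUE)
  sums <- rr$folds$init_checksum
  expect_gt(length(unique(sums)), 1)
  expect_true(leakage_audit(rr, samp)$passed)
})

test_that("protocol violations are detected by the leakage audit", {
  cfg <- micro_cnn_config()
  ck <- fmritransfer:::new_checkpoint(cfg,
                                      get_weights(build_model(cfg, 31)))
  cohort <- make_micro_cohort(n_per_group = 3)
  samp <- preprocess_for(cohort, cfg)
  res <- run_loocv(samp, ck, transfer_spec(epochs = 0, seed = 1,
                                           mode = "transfer"))
  expect_true(leakage_audit(res, samp)$passed)

  # injected duplicate held-out id
  bad <- res
  bad$folds$held_out_id[2] <- bad$folds$held_out_id[1]
  expect_false(leakage_audit(bad)$passed)
  expect_match(leakage_audit(bad)$violations, "duplicate", all = FALSE)

  # injected held-out id inside its own training set
  bad2 <- res
  bad2$provenance$train_ids[[res$folds$held_out_id[3]]] <-
    c(res$folds$held_out_id[3], "tgt-001")
  expect_match(leakage_audit(bad2)$violations, "training set", all = FALSE)

  # injected cohort-level normalization
  bad3 <- res
  bad3$provenance$normalization <- "cohort"
  expect_match(leakage_audit(bad3)$violations, "cohort-level", all = FALSE)

  # a reference arm claiming the source weights is flagged
  badref <- res
  badref$provenance$mode <- "reference"
  expect_match(leakage_audit(badref)$violations, "reference mode",
               all = FALSE)
})

test_that("fold aggregation pools counts and enforces one fold per participant", {
  folds <- data.frame(
    held_out_id = sprintf("p%02d", 1:8),
    true_label = c(1, 1, 1, 1, 0, 0, 0, 0),
    predicted_probability = c(0.9, 0.8, 0.6, 0.2, 0.1, 0.3, 0.4, 0.7),
    predicted_label = c(1, 1, 1, 0, 0, 0, 0, 1))
  agg <- aggregate_folds(folds)
  expect_equal(unclass(agg$confusion)[c("tp", "fp", "tn", "fn")],
               list(tp = 3L, fp = 1L, tn = 3L, fn = 1L))
  expect_equal(agg$metrics$accuracy, 6 / 8)

  perfect <- folds
  perfect$predicted_probability <- ifelse(perfect$true_label == 1, 0.9, 0.1)
  aggp <- aggregate_folds(perfect)
  expect_equal(aggp$metrics$accuracy, 1)
  expect_equal(aggp$metrics$mcc, 1)

  # relabeling the positive class swaps sensitivity and specificity
  flipped <- folds
  flipped$true_label <- 1 - folds$true_label
  flipped$predicted_probability <- 1 - folds$predicted_probability
  aggf <- aggregate_folds(flipped)
  expect_equal(aggf$metrics$sensitivity, agg$metrics$specificity)
  expect_equal(aggf$metrics$specificity, agg$metrics$sensitivity)

  dup <- folds
  dup$held_out_id[2] <- "p01"
  expect_error(aggregate_folds(dup), "protocol violation")
})

test_that("LOOCV validates its inputs", {
  cfg <- micro_cnn_config()
  cohort <- make_micro_cohort(n_per_group = 3)
  samp <- preprocess_for(cohort, cfg)
  expect_error(run_loocv(samp, spec = transfer_spec(mode = "transfer")),
               "requires a source checkpoint")
  expect_error(run_loocv(samp[1], spec = transfer_spec(mode = "reference"),
                         config = cfg), "at least 2")
  # volumes that do not match the architecture are refused
  cfg2 <- micro_cnn_config(grid = 10)
  expect_error(run_loocv(samp, spec = transfer_spec(mode = "reference"),
                         config = cfg2), "resize")
})
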