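test_that("patience rule keeps the best epoch and stops at the right time", {
  es_run <- function(losses, patience) {
    st <- fmritransfer:::early_stop_init(patience)
    ran <- 0L
    for (e in seq_along(losses)) {
      ran <- e
      st <- fmritransfer:::early_stop_update(st, e, losses[e])
      if (st$stop) break
    }
    list(ran = ran, best = st$best_epoch, stopped = st$stop)
  }
  # strictly decreasing loss for 100 epochs: never triggers, best = last
  dec <- es_run(seq(1, 0.01, length.out = 100), patience = 15)
  expect_equal(dec$ran, 100L)
  expect_equal(dec$best, 100L)
  expect_false(dec$stopped)

  # minimum at epoch 3 then flat-worse: stops at epoch 18, keeps epoch 3
  seq3 <- c(0.5, 0.4, 0.3, rep(0.35, 97))
  s3 <- es_run(seq3, patience = 15)
  expect_equal(s3$ran, 18L)
  expect_equal(s3$best, 3L)
  expect_true(s3$stopped)

  # an equal loss is not an improvement (strict comparison)
  flat <- es_run(rep(0.5, 10), patience = 3)
  expect_equal(flat$ran, 4L)
  expect_equal(flat$best, 1L)
})

test_that("source training is deterministic and freezes the minimum-loss epoch", {
  cohort <- tiny_cohort(n_per_group = 6)
  cfg <- tiny_cnn_config()
  samp <- preprocess_for(cohort, cfg)
  labs <- fmritransfer:::sample_labels(samp)
  sp <- split_holdout(labs, seed = 2)
  spec <- train_spec(epochs = 4, batch_size = 4, lr = 1e-3, seed = 5)
  fit1 <- train_source(samp[sp$train], samp[sp$val], spec, cfg)
  fit2 <- train_source(samp[sp$train], samp[sp$val], spec, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$checkpoint$weights, fit2$checkpoint$weights)
  # checkpointed val_loss equals the minimum over recorded epochs
  expect_equal(fit1$checkpoint$val_loss, min(fit1$history$val_loss))
  expect_equal(fit1$checkpoint$epoch,
               which.min(fit1$history$val_loss))
  expect_true(all(is.finite(as.matrix(fit1$history))))
  expect_true(all(fit1$history$val_accuracy >= 0 &
                    fit1$history$val_accuracy <= 1))
})

test_that("a separable cohort is learned to high validation accuracy", {
  fit <- cached("separable_fit", {
    cohort <- tiny_cohort(n_per_group = 20, effect_size = 3,
                          noise_sd = 0.1, seed = 11)
    cfg <- tiny_cnn_config()
    samp <- preprocess_for(cohort, cfg)
    sp <- split_holdout(fmritransfer:::sample_labels(samp), seed = 3)
    list(fit = train_source(samp[sp$train], samp[sp$val],
                            train_spec(epochs = 30, batch_size = 8,
                                       lr = 1e-3, seed = 5), cfg),
         samp = samp, sp = sp)
  })
  best_val_acc <- max(fit$fit$history$val_accuracy)
  expect_gte(best_val_acc, 0.9)
  m <- evaluate_holdout(fit$fit$checkpoint, fit$samp[fit$sp$test])
  expect_gte(m$accuracy, 0.75)
})

test_that("early stopping never worsens the best recorded validation loss", {
  cohort <- tiny_cohort(n_per_group = 6, effect_size = 1, noise_sd = 0.5)
  cfg <- tiny_cnn_config()
  samp <- preprocess_for(cohort, cfg)
  sp <- split_holdout(fmritransfer:::sample_labels(samp), seed = 8)
  run <- function(patience)
    train_source(samp[sp$train], samp[sp$val],
                 train_spec(epochs = 8, batch_size = 5, lr = 2e-3,
                            early_stop_patience = patience, seed = 4),
                 cfg)
  impatient <- run(2)
  full <- run(100)
  # identical epoch records up to the stopping point ...
  k <- nrow(impatient$history)
  expect_equal(impatient$history, full$history[seq_len(k), ],
               tolerance = 1e-12)
  # ... and the longer run can only match or improve the best loss
  expect_lte(full$checkpoint$val_loss, impatient$checkpoint$val_loss)
})

test_that("training rejects overlapping or empty validation sets", {
  cohort <- tiny_cohort(n_per_group = 3)
  cfg <- tiny_cnn_config()
  samp <- preprocess_for(cohort, cfg)
  spec <- train_spec(epochs = 1, batch_size = 2, seed = 1)
  expect_error(train_source(samp[1:4], list(), spec, cfg), "empty")
  expect_error(train_source(samp[1:4], samp[4:5], spec, cfg), "overlap")
})

test_that("hold-out evaluation enforces id disjointness and labels degenerate models", {
  cohort <- tiny_cohort(n_per_group = 4)
  cfg <- tiny_cnn_config()
  samp <- preprocess_for(cohort, cfg)

  # a model forced to predict 'case' for everything
  model <- build_model(cfg, init_seed = 1)
  w <- get_weights(model)
  w$fc2.W[] <- 0
  w$fc2.b[] <- 25
  model <- set_weights(model, w)
  ck <- fmritransfer:::new_checkpoint(cfg, get_weights(model),
                                      provenance = list(train_ids = "x"))
  m <- evaluate_holdout(ck, samp)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0)

  ck_leaky <- fmritransfer:::new_checkpoint(cfg, get_weights(model),
                                            provenance = list(
                                              train_ids =
                                                samp[[1]]$participant_id))
  expect_error(evaluate_holdout(ck_leaky, samp), "leakage")
  expect_error(evaluate_holdout(ck, list()), "empty")
})
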