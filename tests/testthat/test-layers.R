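# Correctness of the dense compute kernels and of the full backward pass.

naive_conv3d <- function(x, w, b) {
  d <- dim(x); wd <- dim(w)
  k <- wd[1]; Cin <- wd[4]; Cout <- wd[5]; N <- d[5]
  O <- d[1] - k + 1
  y <- array(0, c(O, O, O, Cout, N))
  for (n in seq_len(N)) for (co in seq_len(Cout))
    for (oz in seq_len(O)) for (oy in seq_len(O)) for (ox in seq_len(O)) {
      acc <- b[co]
      for (ci in seq_len(Cin))
        acc <- acc + sum(x[ox:(ox + k - 1), oy:(oy + k - 1),
                           oz:(oz + k - 1), ci, n] * w[, , , ci, co])
      y[ox, oy, oz, co, n] <- acc
    }
  y
}

naive_maxpool3d <- function(x, k, s) {
  d <- dim(x)
  O <- (d[1] - k) %/% s + 1
  y <- array(0, c(O, O, O, d[4], d[5]))
  for (n in seq_len(d[5])) for (c in seq_len(d[4]))
    for (oz in seq_len(O)) for (oy in seq_len(O)) for (ox in seq_len(O)) {
      x0 <- (ox - 1) * s + 1; y0 <- (oy - 1) * s + 1; z0 <- (oz - 1) * s + 1
      y[ox, oy, oz, c, n] <- max(x[x0:(x0 + k - 1), y0:(y0 + k - 1),
                                   z0:(z0 + k - 1), c, n])
    }
  y
}

test_that("the GEMM convolution matches a naive loop convolution", {
  set.seed(41)
  x <- array(rnorm(7^3 * 2 * 3), c(7, 7, 7, 2, 3))
  w <- array(rnorm(3^3 * 2 * 4), c(3, 3, 3, 2, 4))
  b <- rnorm(4)
  got <- fmritransfer:::conv3d_forward_cpp(x, w, b)
  expect_equal(got, naive_conv3d(x, w, b), tolerance = 1e-12)
})

test_that("max pooling matches a naive loop and routes gradients to argmax", {
  set.seed(42)
  x <- array(rnorm(8^3 * 2 * 2), c(8, 8, 8, 2, 2))
  r <- fmritransfer:::maxpool3d_forward_cpp(x, 2, 2)
  expect_equal(r$y, naive_maxpool3d(x, 2, 2), tolerance = 1e-12)

  dy <- array(1, dim(r$y))
  dx <- fmritransfer:::maxpool3d_backward_cpp(dy, r$argmax,
                                              as.integer(dim(x)))
  # every pooling window contributes exactly one gradient unit
  expect_equal(sum(dx), length(r$y))
  expect_true(all(dx[dx != 0] >= 1))
})

test_that("analytic gradients match central finite differences everywhere", {
  cfg <- cnn_config(in_channels = 2, conv_channels = 3, conv_kernels = 3,
                    pool_kernels = 2, pool_strides = 2, head_hidden = 4,
                    dropout_p = 0, input_size = 8)
  model <- build_model(cfg, 7)
  set.seed(42)
  n <- 4
  xb <- array(rnorm(8^3 * 2 * n), c(8, 8, 8, 2, n))
  yb <- c(0, 1, 1, 0)
  loss_fn <- function(mm) {
    f <- fmritransfer:::model_forward(mm, xb, training = TRUE)
    fmritransfer:::bce_loss(f$prob, yb)
  }
  fw <- fmritransfer:::model_forward(model, xb, training = TRUE,
                                     keep_cache = TRUE)
  grads <- fmritransfer:::model_backward(fw$model, fw$caches,
                                         (fw$prob - yb) / n)
  expect_length(grads, length(model$layers))
  eps <- 1e-6
  for (li in seq_along(grads)) {
    g <- grads[[li]]
    if (is.null(g)) next
    for (f in names(g)) {
      arr <- model$layers[[li]][[f]]
      for (ii in sample(length(arr), min(4, length(arr)))) {
        m2 <- model; m2$layers[[li]][[f]][ii] <- arr[ii] + eps
        m3 <- model; m3$layers[[li]][[f]][ii] <- arr[ii] - eps
        num <- (loss_fn(m2) - loss_fn(m3)) / (2 * eps)
        rel <- abs(num - g[[f]][ii]) /
          max(1e-5, abs(num) + abs(g[[f]][ii]))
        expect_lt(rel, 1e-4,
                  label = sprintf("layer %d (%s) %s[%d] gradient mismatch",
                                  li, model$layers[[li]]$type, f, ii))
      }
    }
  }
})

test_that("batch-norm running statistics drive eval mode", {
  lf <- fmritransfer:::layer_forward
  layer <- list(type = "bn1d", name = "bn", gamma = c(2, 1),
                beta = c(0.5, 0), running_mean = c(0, 0),
                running_var = c(1, 1), momentum = 0.5, eps = 1e-5)
  set.seed(4)
  x <- matrix(rnorm(20, mean = 3, sd = 2), 10, 2)
  tr <- lf(layer, x, training = TRUE)
  # train-mode output is standardized per column (up to gamma/beta)
  expect_equal(colMeans(tr$y), c(0.5, 0), tolerance = 1e-10)
  # running stats moved half-way toward the batch statistics
  expect_equal(tr$layer$running_mean, 0.5 * colMeans(x), tolerance = 1e-10)
  # eval mode on a single row uses the running statistics and stays finite
  ev <- lf(tr$layer, x[1, , drop = FALSE], training = FALSE)
  expect_true(all(is.finite(ev$y)))
})
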