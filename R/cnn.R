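#' 3D-CNN architecture configuration
#'
#' Describes the simplified C3D-style network used throughout the package:
#' `length(conv_channels)` blocks of
#' `Conv3D -> LeakyReLU -> MaxPool3D -> BatchNorm3D`, a flatten, a hidden
#' linear layer with LeakyReLU and BatchNorm1D, dropout, a final linear
#' unit and a sigmoid. The constructor performs the full layer-by-layer
#' shape arithmetic (valid convolutions, stride-2 pooling with floor
#' division) and errors if any spatial dimension collapses below 1 or if
#' the computed flatten length disagrees with `expected_flatten`; shapes
#' are never silently padded.
#'
#' With the defaults (61 voxels per axis, kernels 6/6/4, pools 6/6/4 at
#' stride 2) the per-axis trace is 61 -> 56 -> 26 -> 21 -> 8 -> 5 -> 1, so
#' the flatten length is exactly `64 * 1^3 = 64`, feeding the 64 -> 20
#' hidden layer.
#'
#' @param in_channels input channels (default 8).
#' @param conv_channels output channels per conv block.
#' @param conv_kernels cubic conv kernel size per block (stride 1, no
#'   padding).
#' @param pool_kernels cubic max-pool kernel size per block.
#' @param pool_strides max-pool stride per block.
#' @param head_hidden hidden width of the classification head.
#' @param dropout_p dropout probability in the head.
#' @param leaky_slope negative slope of the LeakyReLU activations.
#' @param input_size input voxels per axis (cubic).
#' @param bn_momentum running-statistics momentum of the batch-norm layers.
#' @param expected_flatten optional required flatten length; a mismatch is
#'   a construction error reporting the computed value.
#' @return an object of class `cnn_config`.
#' @export
#' @examples
#' cfg <- cnn_config()
#' cfg$flatten_length  # 64
cnn_config <- function(in_channels = 8, conv_channels = c(16, 32, 64),
                       conv_kernels = c(6, 6, 4), pool_kernels = c(6, 6, 4),
                       pool_strides = c(2, 2, 2), head_hidden = 20,
                       dropout_p = 0.5, leaky_slope = 0.01, input_size = 61,
                       bn_momentum = 0.1, expected_flatten = NULL) {
  nb <- length(conv_channels)
  stop_if_not(length(conv_kernels) == nb && length(pool_kernels) == nb &&
                length(pool_strides) == nb,
              "cnn_config: conv_channels, conv_kernels, pool_kernels and pool_strides must have equal length")
  stop_if_not(dropout_p >= 0 && dropout_p < 1,
              "cnn_config: dropout_p must lie in [0, 1)")
  stop_if_not(input_size >= 1, "cnn_config: input_size must be positive")
  sz <- as.integer(input_size)
  trace <- data.frame(layer = "input", size = sz,
                      channels = as.integer(in_channels))
  for (b in seq_len(nb)) {
    sz <- sz - conv_kernels[b] + 1L
    if (sz < 1)
      stop(sprintf("cnn_config: conv block %d (kernel %d) reduces the spatial size below 1",
                   b, conv_kernels[b]), call. = FALSE)
    trace <- rbind(trace, data.frame(layer = sprintf("conv%d", b),
                                     size = sz,
                                     channels = conv_channels[b]))
    if (sz < pool_kernels[b])
      stop(sprintf("cnn_config: pool block %d (kernel %d) does not fit the %d^3 feature map",
                   b, pool_kernels[b], sz), call. = FALSE)
    sz <- (sz - pool_kernels[b]) %/% pool_strides[b] + 1L
    trace <- rbind(trace, data.frame(layer = sprintf("pool%d", b),
                                     size = sz,
                                     channels = conv_channels[b]))
  }
  flatten <- conv_channels[nb] * sz^3
  if (!is.null(expected_flatten) && flatten != expected_flatten)
    stop(sprintf("cnn_config: computed flatten length %d (final map %d^3 x %d channels) != expected %d",
                 flatten, sz, conv_channels[nb], expected_flatten),
         call. = FALSE)
  structure(list(in_channels = as.integer(in_channels),
                 conv_channels = as.integer(conv_channels),
                 conv_kernels = as.integer(conv_kernels),
                 pool_kernels = as.integer(pool_kernels),
                 pool_strides = as.integer(pool_strides),
                 head_hidden = as.integer(head_hidden),
                 dropout_p = dropout_p, leaky_slope = leaky_slope,
                 input_size = as.integer(input_size),
                 bn_momentum = bn_momentum,
                 flatten_length = as.integer(flatten),
                 shape_trace = trace),
            class = "cnn_config")
}

#' @export
print.cnn_config <- function(x, ...) {
  cat("3D-CNN configuration\n")
  nb <- length(x$conv_channels)
  inc <- c(x$in_channels, x$conv_channels)
  rows <- character(0)
  for (b in seq_len(nb)) {
    rows <- c(rows,
              sprintf("Conv3D + LeakyReLU  %4d %4d  %dx%dx%d  stride 1  pad 0",
                      inc[b], inc[b + 1], x$conv_kernels[b],
                      x$conv_kernels[b], x$conv_kernels[b]),
              sprintf("MaxPool3D                      %dx%dx%d  stride %d",
                      x$pool_kernels[b], x$pool_kernels[b],
                      x$pool_kernels[b], x$pool_strides[b]),
              sprintf("BatchNorm3D         %4d", inc[b + 1]))
  }
  rows <- c(rows, "Flatten",
            sprintf("Linear + LeakyReLU  %4d %4d", x$flatten_length,
                    x$head_hidden),
            sprintf("BatchNorm1D         %4d", x$head_hidden),
            sprintf("Dropout             p = %.2f", x$dropout_p),
            sprintf("Linear              %4d    1", x$head_hidden),
            "Sigmoid")
  cat(paste0("  ", rows, collapse = "\n"), "\n")
  cat(sprintf("  input %d^3, flatten length %d\n", x$input_size,
              x$flatten_length))
  invisible(x)
}

kaiming_sd <- function(fan_in, slope) sqrt(2 / ((1 + slope^2) * fan_in))

#' Build a 3D-CNN model with seeded initialization
#'
#' Conv and hidden-linear weights use Kaiming-style normal initialization
#' matched to the LeakyReLU slope; the output unit uses a
#' `Normal(0, 1/sqrt(fan_in))` draw; biases start at zero; batch-norm
#' scales at 1 and shifts at 0. Initialization is a deterministic function
#' of `init_seed`.
#'
#' @param config a [cnn_config()].
#' @param init_seed integer seed for the weight draws.
#' @return an object of class `cnn3d_model`.
#' @export
build_model <- function(config, init_seed = 1) {
  stop_if_not(inherits(config, "cnn_config"),
              "build_model: expected a cnn_config")
  slope <- config$leaky_slope
  layers <- list()
  inc <- config$in_channels
  with_seed(derive_seed(init_seed, "weights"), {
    for (b in seq_along(config$conv_channels)) {
      k <- config$conv_kernels[b]
      outc <- config$conv_channels[b]
      fan_in <- k^3 * inc
      W <- array(rnorm(k^3 * inc * outc, 0, kaiming_sd(fan_in, slope)),
                 c(k, k, k, inc, outc))
      layers[[length(layers) + 1]] <-
        list(type = "conv", name = sprintf("conv%d", b), W = W,
             b = numeric(outc), k = k)
      layers[[length(layers) + 1]] <-
        list(type = "leaky", name = sprintf("act%d", b), slope = slope)
      layers[[length(layers) + 1]] <-
        list(type = "pool", name = sprintf("pool%d", b),
             k = config$pool_kernels[b], s = config$pool_strides[b])
      layers[[length(layers) + 1]] <-
        list(type = "bn3d", name = sprintf("bn%d", b),
             gamma = rep(1, outc), beta = numeric(outc),
             running_mean = numeric(outc), running_var = rep(1, outc),
             momentum = config$bn_momentum, eps = 1e-5)
      inc <- outc
    }
    layers[[length(layers) + 1]] <- list(type = "flatten", name = "flatten")
    F <- config$flatten_length
    H <- config$head_hidden
    layers[[length(layers) + 1]] <-
      list(type = "linear", name = "fc1",
           W = matrix(rnorm(F * H, 0, kaiming_sd(F, slope)), F, H),
           b = numeric(H))
    layers[[length(layers) + 1]] <-
      list(type = "leaky", name = "act_fc1", slope = slope)
    layers[[length(layers) + 1]] <-
      list(type = "bn1d", name = "bn_fc1",
           gamma = rep(1, H), beta = numeric(H),
           running_mean = numeric(H), running_var = rep(1, H),
           momentum = config$bn_momentum, eps = 1e-5)
    layers[[length(layers) + 1]] <-
      list(type = "dropout", name = "dropout", p = config$dropout_p)
    layers[[length(layers) + 1]] <-
      list(type = "linear", name = "fc2",
           W = matrix(rnorm(H, 0, 1 / sqrt(H)), H, 1), b = numeric(1))
  })
  structure(list(config = config, layers = layers, init_seed = init_seed),
            class = "cnn3d_model")
}

# ---- layer forward/backward -------------------------------------------------

bn_channel_stats <- function(x, S, C, N) {
  # x reshaped as (S, C, N); returns per-channel mean and biased variance
  m_cn <- .colMeans(x, S, C * N)
  mu <- .rowMeans(matrix(m_cn, C, N), C, N)
  q_cn <- .colMeans(x * x, S, C * N)
  ex2 <- .rowMeans(matrix(q_cn, C, N), C, N)
  list(mean = mu, var = pmax(ex2 - mu^2, 0))
}

layer_forward <- function(layer, x, training) {
  cache <- NULL
  switch(layer$type,
    conv = {
      y <- conv3d_forward_cpp(x, layer$W, layer$b)
      cache <- list(x = x)
    },
    leaky = {
      neg <- x < 0
      y <- x
      y[neg] <- layer$slope * x[neg]
      cache <- list(neg = neg)
    },
    pool = {
      r <- maxpool3d_forward_cpp(x, layer$k, layer$s)
      y <- r$y
      cache <- list(argmax = r$argmax, xdim = dim(x))
    },
    bn3d = {
      d <- dim(x)
      S <- prod(d[1:3]); C <- d[4]; N <- d[5]
      if (training) {
        st <- bn_channel_stats(x, S, C, N)
        n_el <- S * N
        unb <- if (n_el > 1) st$var * n_el / (n_el - 1) else st$var
        layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
          layer$momentum * st$mean
        layer$running_var <- (1 - layer$momentum) * layer$running_var +
          layer$momentum * unb
        mu <- st$mean; va <- st$var
      } else {
        mu <- layer$running_mean; va <- layer$running_var
      }
      inv <- 1 / sqrt(va + layer$eps)
      mu_r <- rep(mu, each = S)
      inv_r <- rep(inv, each = S)
      xhat <- (x - mu_r) * inv_r           # recycles over N
      y <- xhat * rep(layer$gamma, each = S) + rep(layer$beta, each = S)
      dim(y) <- d
      if (training) cache <- list(xhat = xhat, inv = inv, S = S, C = C,
                                  N = N, d = d)
    },
    bn1d = {
      N <- nrow(x); C <- ncol(x)
      if (training) {
        mu <- .colMeans(x, N, C)
        va <- pmax(.colMeans(x * x, N, C) - mu^2, 0)
        unb <- if (N > 1) va * N / (N - 1) else va
        layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
          layer$momentum * mu
        layer$running_var <- (1 - layer$momentum) * layer$running_var +
          layer$momentum * unb
      } else {
        mu <- layer$running_mean; va <- layer$running_var
      }
      inv <- 1 / sqrt(va + layer$eps)
      xhat <- sweep(x, 2, mu) * rep(inv, each = N)
      y <- sweep(xhat * rep(layer$gamma, each = N), 2, layer$beta, "+")
      if (training) cache <- list(xhat = xhat, inv = inv, N = N, C = C)
    },
    flatten = {
      d <- dim(x)
      N <- d[5]
      y <- matrix(x, nrow = prod(d[1:4]), ncol = N)
      y <- t(y)
      cache <- list(d = d)
    },
    linear = {
      y <- x %*% layer$W
      y <- sweep(y, 2, layer$b, "+")
      cache <- list(x = x)
    },
    dropout = {
      if (training && layer$p > 0) {
        keep <- matrix(runif(length(x)) >= layer$p, nrow(x), ncol(x))
        y <- x * keep / (1 - layer$p)
        cache <- list(keep = keep)
      } else {
        y <- x
        cache <- list(keep = NULL)
      }
    },
    stop("unknown layer type: ", layer$type)
  )
  list(y = y, cache = cache, layer = layer)
}

layer_backward <- function(layer, dy, cache, need_dx = TRUE) {
  grads <- NULL
  switch(layer$type,
    conv = {
      r <- conv3d_backward_cpp(cache$x, layer$W, dy, need_dx)
      dx <- if (need_dx) r$dx else NULL
      grads <- list(W = r$dw, b = r$db)
    },
    leaky = {
      dx <- dy
      dx[cache$neg] <- layer$slope * dy[cache$neg]
    },
    pool = {
      dx <- maxpool3d_backward_cpp(dy, cache$argmax,
                                   as.integer(cache$xdim))
    },
    bn3d = {
      S <- cache$S; C <- cache$C; N <- cache$N
      n_el <- S * N
      csum <- function(v) {
        s_cn <- .colSums(v, S, C * N)
        .rowSums(matrix(s_cn, C, N), C, N)
      }
      dim(dy) <- cache$d
      dgamma <- csum(dy * cache$xhat)
      dbeta <- csum(dy)
      g_inv <- layer$gamma * cache$inv
      mean_dy <- dbeta / n_el
      mean_dyxhat <- dgamma / n_el
      dx <- rep(g_inv, each = S) *
        (dy - rep(mean_dy, each = S) -
           cache$xhat * rep(mean_dyxhat, each = S))
      dim(dx) <- cache$d
      grads <- list(gamma = dgamma, beta = dbeta)
    },
    bn1d = {
      N <- cache$N
      dgamma <- colSums(dy * cache$xhat)
      dbeta <- colSums(dy)
      g_inv <- layer$gamma * cache$inv
      dx <- sweep(dy, 2, dbeta / N) - cache$xhat *
        rep(colSums(dy * cache$xhat) / N, each = N)
      dx <- dx * rep(g_inv, each = N)
      grads <- list(gamma = dgamma, beta = dbeta)
    },
    flatten = {
      dx <- array(t(dy), cache$d)
    },
    linear = {
      grads <- list(W = crossprod(cache$x, dy), b = colSums(dy))
      dx <- tcrossprod(dy, layer$W)
    },
    dropout = {
      dx <- if (is.null(cache$keep)) dy else dy * cache$keep / (1 - layer$p)
    },
    stop("unknown layer type: ", layer$type)
  )
  list(dx = dx, grads = grads)
}

# Forward pass through the whole network.
# x: batch tensor (X, Y, Z, C, N). Returns probabilities, logits, the
# per-layer caches (when keep_cache) and the (possibly updated) model.
model_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  d <- dim(x)
  stop_if_not(length(d) == 5 && d[4] == cfg$in_channels &&
                all(d[1:3] == cfg$input_size),
              "model_forward: expected input %d x %d^3 per sample, got %s",
              cfg$in_channels, cfg$input_size,
              paste(d, collapse = "x"))
  caches <- if (keep_cache) vector("list", length(model$layers)) else NULL
  for (i in seq_along(model$layers)) {
    r <- layer_forward(model$layers[[i]], x, training)
    x <- r$y
    model$layers[[i]] <- r$layer
    if (keep_cache) caches[[i]] <- r$cache
  }
  logit <- as.numeric(x)
  prob <- 1 / (1 + exp(-logit))
  list(prob = prob, logit = logit, caches = caches, model = model)
}

model_backward <- function(model, caches, dlogit) {
  grads <- vector("list", length(model$layers))
  dy <- matrix(dlogit, ncol = 1)
  for (i in rev(seq_along(model$layers))) {
    # the input gradient of the first layer is never consumed; skip it
    r <- layer_backward(model$layers[[i]], dy, caches[[i]],
                        need_dx = i > 1)
    dy <- r$dx
    grads[i] <- list(r$grads)   # not [[<-]]: NULL grads must keep their slot
  }
  grads
}

#' Predict case probabilities from a fitted model
#'
#' Runs an eval-mode forward pass: batch-norm layers use their accumulated
#' running statistics and dropout is disabled, so prediction is a pure
#' function of the weights and the input and is well defined for a single
#' sample (the leave-one-out setting).
#'
#' @param object a `cnn3d_model`.
#' @param newdata a batch tensor `(X, Y, Z, C, N)`, a single
#'   [volume_sample()], or a list of them.
#' @param type `"prob"` for probabilities, `"label"` for thresholded 0/1
#'   labels (ties at 0.5 predict positive).
#' @param ... unused.
#' @return numeric vector of length N.
#' @export
predict.cnn3d_model <- function(object, newdata, type = c("prob", "label"),
                                ...) {
  type <- match.arg(type)
  if (inherits(newdata, "volume_sample")) newdata <- list(newdata)
  if (is.list(newdata)) newdata <- batch_from_samples(newdata)
  p <- model_forward(object, newdata, training = FALSE)$prob
  if (type == "label") as.integer(p >= 0.5) else p
}

#' @export
print.cnn3d_model <- function(x, ...) {
  cat(sprintf("<cnn3d_model  %s trainable parameters, input %d x %d^3>\n",
              format(count_params(x), big.mark = ","),
              x$config$in_channels, x$config$input_size))
  invisible(x)
}

#' @export
summary.cnn3d_model <- function(object, ...) {
  print(object$config)
  cat(sprintf("Trainable parameters: %s\n",
              format(count_params(object), big.mark = ",")))
  invisible(object)
}

trainable_names <- c(conv = "W,b", linear = "W,b", bn3d = "gamma,beta",
                     bn1d = "gamma,beta")

#' Total number of trainable parameters
#' @param model a `cnn3d_model`.
#' @return integer count over conv/linear weights and biases and batch-norm
#'   scale/shift parameters (running statistics excluded).
#' @export
count_params <- function(model) {
  tot <- 0
  for (ly in model$layers) {
    nms <- trainable_names[ly$type]
    if (is.na(nms)) next
    for (f in strsplit(nms, ",")[[1]]) tot <- tot + length(ly[[f]])
  }
  as.integer(tot)
}

# ---- weights as a flat named list ------------------------------------------

weight_fields <- function(type) {
  switch(type,
         conv = c("W", "b"),
         linear = c("W", "b"),
         bn3d = c("gamma", "beta", "running_mean", "running_var"),
         bn1d = c("gamma", "beta", "running_mean", "running_var"),
         character(0))
}

#' Extract all model state as a flat named list of arrays
#' @param model a `cnn3d_model`.
#' @return named list `"<layer>.<field>"` including batch-norm running
#'   statistics.
#' @export
get_weights <- function(model) {
  out <- list()
  for (ly in model$layers)
    for (f in weight_fields(ly$type))
      out[[paste(ly$name, f, sep = ".")]] <- ly[[f]]
  out
}

#' Set model state from a flat named list of arrays
#'
#' Names and array shapes must match the model's architecture exactly;
#' any discrepancy is an architecture-mismatch error.
#'
#' @param model a `cnn3d_model`.
#' @param weights a list as returned by [get_weights()].
#' @return the updated model.
#' @export
set_weights <- function(model, weights) {
  expected <- get_weights(model)
  if (!setequal(names(expected), names(weights)))
    stop(sprintf("set_weights: architecture mismatch; missing [%s], unexpected [%s]",
                 paste(setdiff(names(expected), names(weights)),
                       collapse = ", "),
                 paste(setdiff(names(weights), names(expected)),
                       collapse = ", ")), call. = FALSE)
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    for (f in weight_fields(ly$type)) {
      nm <- paste(ly$name, f, sep = ".")
      new <- weights[[nm]]
      old <- ly[[f]]
      if (!identical(dim(new) %||% length(new), dim(old) %||% length(old)))
        stop(sprintf("set_weights: architecture mismatch at %s: saved %s vs model %s",
                     nm, paste(dim(new) %||% length(new), collapse = "x"),
                     paste(dim(old) %||% length(old), collapse = "x")),
             call. = FALSE)
      model$layers[[i]][[f]] <- new
    }
  }
  model
}

# ---- checkpointing ----------------------------------------------------------

#' Save a model checkpoint
#'
#' A checkpoint freezes the complete model state (config, all parameters,
#' batch-norm running statistics) together with the epoch it came from, its
#' validation loss and free-form provenance. Save/load round-trips are
#' bitwise exact.
#'
#' @param model a `cnn3d_model`.
#' @param path output file.
#' @param epoch,val_loss metadata of the frozen epoch.
#' @param provenance named list (run id, seeds, ...).
#' @return invisibly, the checkpoint object (class `cnn_checkpoint`).
#' @export
save_checkpoint <- function(model, path, epoch = NA_integer_,
                            val_loss = NA_real_, provenance = list()) {
  ck <- new_checkpoint(model$config, get_weights(model), epoch, val_loss,
                       provenance)
  saveRDS(ck, path)
  invisible(ck)
}

new_checkpoint <- function(config, weights, epoch = NA_integer_,
                           val_loss = NA_real_, provenance = list()) {
  structure(list(config = config, weights = weights,
                 epoch = as.integer(epoch), val_loss = val_loss,
                 provenance = provenance),
            class = "cnn_checkpoint")
}

#' Load a model checkpoint
#' @param path file written by [save_checkpoint()].
#' @return a `cnn_checkpoint`.
#' @export
load_checkpoint <- function(path) {
  stop_if_not(file.exists(path), "load_checkpoint: no such file: %s", path)
  ck <- tryCatch(readRDS(path), error = function(e)
    stop(sprintf("load_checkpoint: corrupt checkpoint %s: %s", path,
                 conditionMessage(e)), call. = FALSE))
  stop_if_not(inherits(ck, "cnn_checkpoint") && is.list(ck$weights) &&
                inherits(ck$config, "cnn_config"),
              "load_checkpoint: %s is not a model checkpoint", path)
  ck
}

#' Instantiate a model from a checkpoint
#'
#' @param checkpoint a `cnn_checkpoint`.
#' @param config optional config the weights must fit (defaults to the
#'   checkpoint's own); a mismatch fails loudly.
#' @return a `cnn3d_model` carrying the checkpoint's exact state.
#' @export
restore_model <- function(checkpoint, config = NULL) {
  stop_if_not(inherits(checkpoint, "cnn_checkpoint"),
              "restore_model: expected a cnn_checkpoint")
  config <- config %||% checkpoint$config
  model <- build_model(config, init_seed = 0)
  set_weights(model, checkpoint$weights)
}

#' @export
print.cnn_checkpoint <- function(x, ...) {
  cat(sprintf("<cnn_checkpoint  epoch %s, val_loss %s, %d arrays>\n",
              x$epoch, format(x$val_loss, digits = 4), length(x$weights)))
  invisible(x)
}
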