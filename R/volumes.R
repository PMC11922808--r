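#' A single participant's multi-channel 3D volume
#'
#' The canonical sample container: a dense numeric array shaped
#' `channels x X x Y x Z` plus a binary diagnosis label. A 3D array is
#' promoted to a single-channel 4D array.
#'
#' @param data numeric array, 3D (`X x Y x Z`) or 4D
#'   (`channels x X x Y x Z`); must be finite.
#' @param participant_id unique participant identifier.
#' @param label 0 (control) or 1 (case).
#' @param source_path optional file of origin.
#' @return an object of class `volume_sample`.
#' @export
volume_sample <- function(data, participant_id, label, source_path = NULL) {
  stop_if_not(is.numeric(data) && length(dim(data)) %in% c(3L, 4L),
              "volume_sample: data must be a 3D or 4D numeric array")
  if (length(dim(data)) == 3L) dim(data) <- c(1L, dim(data))
  stop_if_not(all(is.finite(data)), "volume_sample: data must be finite")
  stop_if_not(length(label) == 1 && label %in% c(0, 1),
              "volume_sample: label must be 0 or 1")
  structure(list(participant_id = as.character(participant_id),
                 label = as.integer(label), data = data,
                 source_path = source_path),
            class = "volume_sample")
}

#' @export
print.volume_sample <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_sample %s  label=%d  %d channel(s), %dx%dx%d voxels>\n",
              x$participant_id, x$label, d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Load a participant volume from a NIfTI file
#'
#' 4D files are read as `X x Y x Z x channels` and permuted to the package's
#' channel-first layout; 3D files get a singleton channel axis. Values are
#' read at the file's precision (the generator writes float32).
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`) with 3 or 4 dimensions.
#' @param label binary label to attach.
#' @param participant_id identifier; defaults to the file stem.
#' @return a [volume_sample()].
#' @export
load_volume <- function(path, label,
                        participant_id = sub("\\.nii(\\.gz)?$", "",
                                             basename(path))) {
  stop_if_not(file.exists(path), "load_volume: no such file: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("load_volume: cannot read %s: %s",
                                 path, conditionMessage(e)), call. = FALSE))
  arr <- as.array(img)
  nd <- length(dim(arr))
  if (nd == 3L) {
    dim(arr) <- c(1L, dim(arr))
  } else if (nd == 4L) {
    arr <- aperm(arr, c(4L, 1L, 2L, 3L))
  } else {
    stop(sprintf("load_volume: %s has %d dimensions; expected 3 or 4",
                 path, nd), call. = FALSE)
  }
  out <- volume_sample(arr, participant_id, label, source_path = path)
  attr(out, "affine") <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  out
}

#' Transform configuration
#'
#' Mirrors the preprocessing/augmentation hyperparameters of the training
#' recipes: per-volume intensity normalization with `center`/`scale`
#' (defaults 0.5, 0.25), trilinear resizing to a cubic grid (default 61 per
#' axis), and the two stochastic augmentations (random rotation, random
#' left-right flip) with their probabilities. Deterministic transforms are
#' applied once at load time (resize, then normalize); the stochastic ones
#' are redrawn every training epoch.
#'
#' @param normalize_center,normalize_scale affine normalization applied
#'   after min-max rescaling to `[0, 1]`.
#' @param resize_to target voxels per axis (>= 8).
#' @param rotate_prob,flip_prob augmentation probabilities in `[0, 1]`.
#' @param max_rotate_deg maximum rotation magnitude in degrees.
#' @return an object of class `transform_spec`.
#' @export
transform_spec <- function(normalize_center = 0.5, normalize_scale = 0.25,
                           resize_to = 61, rotate_prob = 0.5, flip_prob = 0,
                           max_rotate_deg = 15) {
  stop_if_not(normalize_scale > 0, "transform_spec: scale must be positive")
  stop_if_not(resize_to >= 8, "transform_spec: resize_to must be >= 8")
  for (p in c(rotate_prob, flip_prob))
    stop_if_not(p >= 0 && p <= 1,
                "transform_spec: probabilities must lie in [0, 1]")
  structure(list(normalize_center = normalize_center,
                 normalize_scale = normalize_scale,
                 resize_to = as.integer(resize_to),
                 rotate_prob = rotate_prob, flip_prob = flip_prob,
                 max_rotate_deg = max_rotate_deg),
            class = "transform_spec")
}

#' Per-volume intensity normalization
#'
#' Rescales the whole sample (all channels jointly) to `[0, 1]` by its
#' min-max range, then applies `(x - center) / scale`. With the default
#' center 0.5 and scale 0.25 the output spans exactly `[-2, 2]`. A
#' constant-valued volume maps to `(0 - center) / scale` everywhere. The
#' statistics are strictly per-volume, so no cohort-level information can
#' leak across cross-validation folds.
#'
#' @param sample a [volume_sample()].
#' @param center,scale normalization constants.
#' @return the normalized [volume_sample()].
#' @export
vol_normalize <- function(sample, center = 0.5, scale = 0.25) {
  stop_if_not(inherits(sample, "volume_sample"),
              "vol_normalize: expected a volume_sample")
  x <- sample$data
  rng <- range(x)
  if (rng[1] == rng[2]) {
    x[] <- (0 - center) / scale
  } else {
    x <- ((x - rng[1]) / (rng[2] - rng[1]) - center) / scale
  }
  sample$data <- x
  sample
}

#' Trilinear resize to a target grid
#'
#' Each channel is resampled independently by trilinear interpolation
#' (half-voxel aligned coordinate mapping, edge-clamped). When the input
#' already has the target shape the sample is returned unchanged, bit for
#' bit.
#'
#' @param sample a [volume_sample()].
#' @param target_shape one integer (cubic) or three integers per axis.
#' @return the resized [volume_sample()].
#' @export
vol_resize <- function(sample, target_shape) {
  stop_if_not(inherits(sample, "volume_sample"),
              "vol_resize: expected a volume_sample")
  if (length(target_shape) == 1) target_shape <- rep(target_shape, 3)
  stop_if_not(length(target_shape) == 3 && all(target_shape >= 1),
              "vol_resize: target shape must be three positive integers")
  target_shape <- as.integer(target_shape)
  d <- dim(sample$data)
  if (all(d[2:4] == target_shape)) return(sample)
  out <- array(0, c(d[1], target_shape))
  for (c in seq_len(d[1]))
    out[c, , , ] <- trilinear_resize_cpp(array(sample$data[c, , , ], d[2:4]),
                                         target_shape)
  sample$data <- out
  sample
}

#' Random 3D rotation augmentation
#'
#' With probability `prob`, rotates the volume by an angle drawn uniformly
#' from `[-max_deg, +max_deg]` about one uniformly chosen spatial axis
#' (all channels share the draw), using trilinear interpolation;
#' out-of-bounds voxels are filled with the channel's minimum (its
#' background value). Otherwise the input is returned unchanged. Draws come
#' from R's session RNG, so results are reproducible under [set.seed()].
#'
#' @param sample a [volume_sample()].
#' @param prob rotation probability.
#' @param max_deg maximum magnitude in degrees.
#' @param angle,axis optional forced angle/axis (used by tests); when given,
#'   no random draw is made for that component.
#' @return a [volume_sample()].
#' @export
random_rotate <- function(sample, prob = 0.5, max_deg = 15,
                          angle = NULL, axis = NULL) {
  stop_if_not(inherits(sample, "volume_sample"),
              "random_rotate: expected a volume_sample")
  if (prob < 1 && runif(1) >= prob) return(sample)
  if (is.null(axis)) axis <- sample.int(3, 1)
  if (is.null(angle)) angle <- runif(1, -max_deg, max_deg)
  d <- dim(sample$data)
  for (c in seq_len(d[1])) {
    vol <- array(sample$data[c, , , ], d[2:4])
    sample$data[c, , , ] <- rotate3d_cpp(vol, axis, angle, min(vol))
  }
  sample
}

#' Random left-right flip augmentation
#'
#' With probability `prob`, mirrors the volume along the first spatial axis
#' (the left-right axis by convention). Applying the flip twice restores
#' the original array exactly.
#'
#' @param sample a [volume_sample()].
#' @param prob flip probability.
#' @param flip optional forced decision (used by tests).
#' @return a [volume_sample()].
#' @export
random_flip <- function(sample, prob = 0.5, flip = NULL) {
  stop_if_not(inherits(sample, "volume_sample"),
              "random_flip: expected a volume_sample")
  if (is.null(flip)) flip <- runif(1) < prob
  if (!flip) return(sample)
  d <- dim(sample$data)
  sample$data <- sample$data[, d[2]:1, , , drop = FALSE]
  sample
}

#' Label-stratified hold-out split
#'
#' Partitions sample indices into train/validation/test sets with the given
#' fractions, stratified by label. Within each class, split sizes follow
#' largest-remainder rounding (remainder ties are broken toward the split
#' currently furthest below its overall target), which reproduces e.g.
#' 420/52/52 for 524 balanced samples at 80/10/10. The partition is a
#' deterministic function of the labels and the seed.
#'
#' @param labels binary label vector (one per sample).
#' @param fractions three non-negative fractions summing to 1.
#' @param seed integer seed for the within-class shuffle.
#' @return a list with integer index vectors `train`, `val`, `test`.
#' @export
split_holdout <- function(labels, fractions = c(0.8, 0.1, 0.1), seed = 1) {
  stop_if_not(length(fractions) == 3 && all(fractions >= 0) &&
                abs(sum(fractions) - 1) < 1e-8,
              "split_holdout: fractions must be three values summing to 1")
  stop_if_not(all(labels %in% c(0, 1)), "split_holdout: labels must be 0/1")
  n <- length(labels)
  global_target <- largest_remainder(n * fractions)
  alloc <- matrix(0L, nrow = 2, ncol = 3,
                  dimnames = list(c("0", "1"), c("train", "val", "test")))
  for (cl in c(0, 1)) {
    ncl <- sum(labels == cl)
    if (ncl == 0) next
    quota <- ncl * fractions
    base <- floor(quota)
    extra <- ncl - sum(base)
    rem <- quota - base
    take <- integer(0)
    for (i in seq_len(extra)) {
      deficit <- global_target - colSums(alloc) - base
      cand <- setdiff(order(-rem, -deficit), take)
      take <- c(take, cand[1])
      rem[cand[1]] <- -1
    }
    base[take] <- base[take] + 1L
    alloc[as.character(cl), ] <- base
  }
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  for (cl in c(0, 1)) {
    idx <- which(labels == cl)
    if (!length(idx)) next
    idx <- with_seed(derive_seed(seed, "split", cl), sample(idx))
    sizes <- alloc[as.character(cl), ]
    out$train <- c(out$train, idx[seq_len(sizes[1])])
    out$val <- c(out$val, idx[seq_len(sizes[2]) + sizes[1]])
    out$test <- c(out$test, idx[seq_len(sizes[3]) + sizes[1] + sizes[2]])
  }
  sizes <- vapply(out, length, 1L)
  bad <- fractions > 0 & sizes == 0
  if (any(bad))
    stop(sprintf("split_holdout: split(s) %s received no samples; too few samples for the requested fractions",
                 paste(names(out)[bad], collapse = ", ")), call. = FALSE)
  lapply(out, sort)
}

largest_remainder <- function(quota) {
  base <- floor(quota)
  extra <- round(sum(quota)) - sum(base)
  if (extra > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  as.integer(base)
}

# Stack a list of volume_samples into the internal batch tensor
# (X, Y, Z, C, N); channel counts must agree.
batch_from_samples <- function(samples) {
  stop_if_not(length(samples) > 0, "batch_from_samples: empty sample list")
  dims <- vapply(samples, function(s) dim(s$data), integer(4))
  stop_if_not(all(dims == dims[, 1]),
              "batch_from_samples: inconsistent sample dimensions")
  d <- dims[, 1]
  out <- array(0, c(d[2], d[3], d[4], d[1], length(samples)))
  for (i in seq_along(samples))
    out[, , , , i] <- aperm(samples[[i]]$data, c(2, 3, 4, 1))
  out
}

# Apply the deterministic transforms (resize -> normalize) to a list of
# samples; this is the preprocessing order used throughout the pipeline.
preprocess_samples <- function(samples, tf) {
  lapply(samples, function(s)
    vol_normalize(vol_resize(s, tf$resize_to),
                  tf$normalize_center, tf$normalize_scale))
}

# ---- internal channel-last fast path ----------------------------------------
# The training loops keep samples as plain (X, Y, Z, C) arrays: channel
# slices are then contiguous for the resampling kernels and batch assembly
# is a straight memory copy. Sample-facing functions stay channel-first.

to_xyzc <- function(sample) aperm(sample$data, c(2, 3, 4, 1))

# One augmentation draw per sample (rotation accept/axis/angle, flip),
# consuming the session RNG.
draw_augment <- function(tf) {
  rot <- tf$rotate_prob >= 1 || runif(1) < tf$rotate_prob
  axis <- 0L
  angle <- 0
  if (rot) {
    axis <- sample.int(3, 1)
    angle <- runif(1, -tf$max_rotate_deg, tf$max_rotate_deg)
  }
  flip <- tf$flip_prob > 0 &&
    (tf$flip_prob >= 1 || runif(1) < tf$flip_prob)
  list(rotate = rot, axis = axis, angle = angle, flip = flip)
}

apply_augment_xyzc <- function(a, dr) {
  d <- dim(a)
  if (dr$rotate) {
    for (c in seq_len(d[4])) {
      v <- a[, , , c]
      dim(v) <- d[1:3]
      a[, , , c] <- rotate3d_cpp(v, dr$axis, dr$angle, min(v))
    }
  }
  if (dr$flip) a <- a[d[1]:1, , , , drop = FALSE]
  a
}

# Augment each (X, Y, Z, C) array and stack into a (X, Y, Z, C, N) batch.
augment_batch_xyzc <- function(xs, tf) {
  d <- dim(xs[[1]])
  len <- prod(d)
  out <- array(0, c(d, length(xs)))
  for (i in seq_along(xs))
    out[(i - 1) * len + seq_len(len)] <-
      apply_augment_xyzc(xs[[i]], draw_augment(tf))
  out
}

batch_xyzc <- function(xs) {
  d <- dim(xs[[1]])
  len <- prod(d)
  out <- array(0, c(d, length(xs)))
  for (i in seq_along(xs)) out[(i - 1) * len + seq_len(len)] <- xs[[i]]
  out
}
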