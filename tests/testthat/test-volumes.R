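test_that("per-volume normalization maps the range onto [-2, 2]", {
  # midpoint of a [0, 2] volume lands exactly on 0
  v <- volume_sample(array(c(0, 1, 2, 1, 1, 1, 1, 1), c(2, 2, 2)), "a", 0)
  out <- vol_normalize(v)
  expect_equal(out$data[1, 2, 1, 1], 0)

  # constant volume maps to (0 - center)/scale everywhere
  const <- volume_sample(array(7, c(2, 3, 4, 5)), "b", 1)
  expect_true(all(vol_normalize(const)$data == -2))

  # random volume: output min/max are exactly -2 and +2
  set.seed(2)
  r <- volume_sample(array(rnorm(4 * 5^3), c(4, 5, 5, 5)), "c", 0)
  rn <- vol_normalize(r)
  expect_equal(range(rn$data), c(-2, 2), tolerance = 1e-12)
})

test_that("trilinear resize is identity at matched shape and exact on constants", {
  set.seed(3)
  s <- volume_sample(array(rnorm(2 * 9^3), c(2, 9, 9, 9)), "a", 0)
  expect_identical(vol_resize(s, 9)$data, s$data)

  const <- volume_sample(array(3.5, c(1, 8, 8, 8)), "b", 0)
  out <- vol_resize(const, c(5, 7, 11))
  expect_equal(dim(out$data), c(1L, 5L, 7L, 11L))
  expect_true(all(abs(out$data - 3.5) < 1e-12))

  expect_error(vol_resize(s, 0), "positive")
})

test_that("resize moves a blob peak to its rescaled coordinates", {
  g <- 64
  ctr <- c(40, 22, 51)
  ax <- seq_len(g)
  d2 <- outer(outer((ax - ctr[1])^2, (ax - ctr[2])^2, "+"),
              (ax - ctr[3])^2, "+")
  blob <- volume_sample(array(exp(-d2 / 18), c(1, g, g, g)), "p", 0)
  out <- vol_resize(blob, 61)
  peak <- arrayInd(which.max(out$data), dim(out$data))[2:4]
  # independent coordinate mapping: out = (in + 0.5) * 61/64 - 0.5 (1-based)
  expected <- ((ctr - 0.5) * 61 / 64 - 0.5) + 1
  expect_true(all(abs(peak - expected) <= 2))
})

test_that("rotation honours probability, zero angle, and seeded determinism", {
  set.seed(4)
  s <- volume_sample(array(rnorm(2 * 10^3), c(2, 10, 10, 10)), "a", 0)
  expect_identical(random_rotate(s, prob = 0)$data, s$data)
  r0 <- random_rotate(s, prob = 1, angle = 0, axis = 2)
  expect_lt(max(abs(r0$data - s$data)), 1e-5)

  a <- with_seed_test(99, random_rotate(s, prob = 1, max_deg = 15))
  b <- with_seed_test(99, random_rotate(s, prob = 1, max_deg = 15))
  expect_identical(a$data, b$data)
})

test_that("90-degree rotation about z permutes coordinates as expected", {
  g <- 11
  arr <- array(0, c(1, g, g, g))
  arr[1, 9, 6, 6] <- 1   # on the +x axis relative to the center (6,6,6)
  s <- volume_sample(arr, "p", 0)
  r <- random_rotate(s, prob = 1, angle = 90, axis = 3)
  peak <- arrayInd(which.max(r$data), dim(r$data))[2:4]
  # output voxel (6, 9, 6) pulls from input (9, 6, 6) under the inverse map
  expect_equal(peak, c(6L, 9L, 6L))
})

test_that("flip is an involution that mirrors the center of mass", {
  set.seed(6)
  arr <- array(runif(2 * 8 * 6 * 7), c(2, 8, 6, 7))
  arr[1, 2, 3, 4] <- 5  # asymmetric
  s <- volume_sample(arr, "a", 0)
  expect_identical(random_flip(s, prob = 0)$data, arr)
  f2 <- random_flip(random_flip(s, flip = TRUE), flip = TRUE)
  expect_identical(f2$data, arr)

  # center of mass along the flipped axis mirrors about the midpoint
  f <- random_flip(s, flip = TRUE)
  com <- function(a) sum(seq_len(dim(a)[2]) * apply(a, 2, sum)) / sum(a)
  expect_equal(com(f$data), dim(arr)[2] + 1 - com(arr), tolerance = 1e-12)
})

test_that("hold-out split applies largest-remainder rounding and stratifies", {
  labels524 <- rep(c(0, 1), each = 262)
  sp <- split_holdout(labels524, seed = 9)
  expect_equal(lengths(sp), c(train = 420L, val = 52L, test = 52L))
  # stratification: each split is label-balanced for balanced input
  expect_equal(sum(labels524[sp$train]), 210)

  sp10 <- split_holdout(rep(c(0, 1), 5), seed = 1)
  expect_equal(lengths(sp10), c(train = 8L, val = 1L, test = 1L))

  expect_identical(split_holdout(labels524, seed = 9), sp)
  expect_false(identical(split_holdout(labels524, seed = 10), sp))
})

test_that("split partitions are disjoint and exhaustive for random inputs", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(30:200, 1)
    labels <- sample(0:1, n, replace = TRUE, prob = c(0.6, 0.4))
    sp <- split_holdout(labels, seed = i)
    all_idx <- c(sp$train, sp$val, sp$test)
    expect_equal(sort(all_idx), seq_len(n))
    expect_equal(length(all_idx), length(unique(all_idx)))
  }
  expect_error(split_holdout(c(0, 1), fractions = c(0.5, 0.4, 0.1)),
               "no samples")
})

test_that("NIfTI volumes round-trip through export and load at float32", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(grid_size = 8, n_channels = 2,
                         n_components_per_channel = 1, n_per_group = 2,
                         noise_sd = 0.2, seed = 21)
  cohort <- generate_cohort(spec, make_component_atlas(spec), 1)
  export_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  expect_true(file.exists(file.path(dir, "provenance.json")))

  back <- load_cohort(dir)
  expect_equal(back$labels$label, cohort$labels$label)
  for (i in seq_along(back$samples)) {
    expect_equal(dim(back$samples[[i]]$data), dim(cohort$samples[[i]]$data))
    expect_equal(back$samples[[i]]$data, cohort$samples[[i]]$data,
                 tolerance = 1e-6)   # float32 storage
  }

  # 3D file gains a singleton channel axis
  p3 <- file.path(dir, "vol3d.nii.gz")
  RNifti::writeNifti(array(rnorm(8^3), c(8, 8, 8)), p3)
  v3 <- load_volume(p3, label = 0)
  expect_equal(dim(v3$data)[1], 1L)

  # 5D file is rejected with a format error naming the path
  p5 <- file.path(dir, "vol5d.nii.gz")
  RNifti::writeNifti(array(0, c(4, 4, 4, 2, 2)), p5)
  expect_error(load_volume(p5, label = 0), "5 dimensions")
  expect_error(load_volume(file.path(dir, "nope.nii"), 0), "no such file")
})
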