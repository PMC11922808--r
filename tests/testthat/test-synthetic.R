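test_that("component atlas maps are peak-normalized, complete and reproducible", {
  spec1 <- synthetic_spec(grid_size = 16, n_channels = 1,
                          n_components_per_channel = 1, n_per_group = 2,
                          seed = 7)
  atlas1 <- make_component_atlas(spec1)
  expect_length(atlas1$maps, 1)
  expect_equal(max(atlas1$maps[[1]]), 1.0)
  expect_true(all(atlas1$maps[[1]] >= 0))

  spec <- synthetic_spec(grid_size = 61, n_channels = 8,
                         n_components_per_channel = 7, seed = 3)
  atlas <- make_component_atlas(spec)
  expect_length(atlas$maps, 56)   # 8 channels x 7 components
  expect_equal(atlas$channel, rep(1:8, each = 7))

  again <- make_component_atlas(spec)
  expect_identical(atlas$maps, again$maps)
  expect_identical(atlas$centers, again$centers)

  # centers within a channel respect the 4-voxel separation
  for (c in 1:8) {
    ctrs <- atlas$centers[atlas$channel == c, ]
    expect_gte(min(dist(ctrs)), 4)
  }
})

test_that("atlas construction fails on grids too small for the request", {
  spec <- synthetic_spec(grid_size = 8, n_channels = 1,
                         n_components_per_channel = 60, seed = 1)
  expect_error(make_component_atlas(spec), "cannot place")
})

test_that("cohorts are balanced with matched null classes", {
  spec <- synthetic_spec(grid_size = 8, n_channels = 1,
                         n_components_per_channel = 1, n_per_group = 32,
                         effect_size = 0, noise_sd = 0, seed = 5)
  atlas <- make_component_atlas(spec)
  cohort <- expect_warning(generate_cohort(spec, atlas, integer(0)),
                           regexp = NA)
  expect_length(cohort$samples, 64)
  expect_equal(sum(cohort$labels$label == 0), 32)
  expect_equal(sum(cohort$labels$label == 1), 32)
  expect_false(anyDuplicated(cohort$labels$participant_id) > 0)

  # effect 0, noise 0: case j and control j are voxel-for-voxel identical
  expect_identical(cohort$samples[[1]]$data, cohort$samples[[33]]$data)
  expect_identical(cohort$samples[[32]]$data, cohort$samples[[64]]$data)

  # empty affected set with nonzero effect warns about the missing signal
  spec2 <- synthetic_spec(grid_size = 8, n_channels = 1,
                          n_components_per_channel = 1, n_per_group = 2,
                          effect_size = 1, seed = 5)
  expect_warning(generate_cohort(spec2, atlas, integer(0)),
                 "no discriminative signal")
})

test_that("class mean difference inside affected components scales with effect size", {
  effects <- c(0.5, 1, 2)
  diffs <- vapply(effects, function(es) {
    spec <- synthetic_spec(grid_size = 12, n_channels = 2,
                           n_components_per_channel = 1, n_per_group = 50,
                           effect_size = es, noise_sd = 0.1, seed = 13)
    atlas <- make_component_atlas(spec)
    cohort <- generate_cohort(spec, atlas, affected_components = 1)
    labs <- cohort$labels$label
    # brute-force group means of channel 1 over the component's support
    mask <- atlas$maps[[1]] > 0.5
    mean_in <- vapply(cohort$samples, function(s)
      mean(s$data[1, , , ][mask]), numeric(1))
    mean(mean_in[labs == 1]) - mean(mean_in[labs == 0])
  }, numeric(1))
  # expected difference = effect_size x mean map value on the support
  spec <- synthetic_spec(grid_size = 12, n_channels = 2,
                         n_components_per_channel = 1, n_per_group = 50,
                         seed = 13)
  atlas <- make_component_atlas(spec)
  mref <- mean(atlas$maps[[1]][atlas$maps[[1]] > 0.5])
  expect_equal(diffs, effects * mref, tolerance = 0.05)
  # linearity: the three points lie on a line through the origin
  expect_gt(cor(diffs, effects)^2, 0.999)
  expect_lt(abs(unname(coef(lm(diffs ~ effects))[1])), 0.02)
})

test_that("transfer pairs share exactly the requested fraction of affected components", {
  mk <- function(seed = 1, n_per_group = 2)
    synthetic_spec(grid_size = 10, n_channels = 2,
                   n_components_per_channel = 4, n_per_group = n_per_group,
                   noise_sd = 0.1, seed = seed)
  pair1 <- generate_transfer_pair(mk(1), mk(2), shared_fraction = 1,
                                  n_affected = 4)
  expect_identical(pair1$provenance$source_affected,
                   pair1$provenance$target_affected)

  pair0 <- generate_transfer_pair(mk(1), mk(2), shared_fraction = 0,
                                  n_affected = 4)
  expect_length(pair0$provenance$overlap, 0)

  pair_half <- generate_transfer_pair(mk(1), mk(2), shared_fraction = 0.5,
                                      n_affected = 4)
  expect_length(pair_half$provenance$overlap, 2)

  bad <- synthetic_spec(grid_size = 12, n_channels = 2,
                        n_components_per_channel = 4, n_per_group = 2)
  expect_error(generate_transfer_pair(mk(1), bad), "grid_size")
})

test_that("spec invariants are validated at construction", {
  expect_error(synthetic_spec(grid_size = 4), "grid_size")
  expect_error(synthetic_spec(n_per_group = 1), "n_per_group")
  expect_error(synthetic_spec(shared_fraction = 1.2), "shared_fraction")
  expect_error(synthetic_spec(noise_sd = -1), "noise_sd")
  expect_error(synthetic_spec(effect_size = Inf), "effect_size")
})
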