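# Shared fixtures: everything is generated in code at test time.

with_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# Independent from-the-definition metrics oracle, deliberately written as
# plain formula transcription (no shared code with compute_metrics).
oracle_metrics <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  div <- function(a, b) if (b == 0) 0 else a / b
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(accuracy = (tp + tn) / n,
       sensitivity = div(tp, tp + fn),
       specificity = div(tn, tn + fp),
       precision = div(tp, tp + fp),
       f1 = div(2 * tp, 2 * tp + fp + fn),
       mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den)
}

# tiny two-block architecture for fast training tests (grid 16)
tiny_cnn_config <- function(grid = 16, in_channels = 2)
  cnn_config(in_channels = in_channels, conv_channels = c(8, 16),
             conv_kernels = c(3, 3), pool_kernels = c(2, 2),
             pool_strides = c(2, 2), input_size = grid)

# minimal architecture for very fast LOOCV protocol tests (grid 12)
micro_cnn_config <- function(grid = 12, in_channels = 1)
  cnn_config(in_channels = in_channels, conv_channels = c(4, 8),
             conv_kernels = c(3, 3), pool_kernels = c(2, 2),
             pool_strides = c(2, 2), input_size = grid)

# small separable cohort on a 16^3 grid, preprocessed for tiny_cnn_config
tiny_cohort <- function(n_per_group = 8, effect_size = 3, noise_sd = 0.1,
                        seed = 11, grid = 16, n_channels = 2) {
  spec <- synthetic_spec(grid_size = grid, n_channels = n_channels,
                         n_components_per_channel = 3,
                         n_per_group = n_per_group,
                         effect_size = effect_size, noise_sd = noise_sd,
                         seed = seed)
  atlas <- make_component_atlas(spec)
  generate_cohort(spec, atlas, affected_components = c(1, 4))
}

preprocess_for <- function(cohort, config)
  fmritransfer:::preprocess_samples(cohort$samples,
                                    transform_spec(resize_to =
                                                     config$input_size))

# Cache for the expensive scaled transfer experiment shared by the
# acceptance tests (computed once per test run).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}
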