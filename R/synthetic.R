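#' Specification of a synthetic spatial-map cohort
#'
#' The generator emulates the output of spatially constrained ICA feature
#' extraction on resting-state fMRI: for every participant, one
#' multi-channel 3D volume whose channels are brain-network spatial maps
#' built from smooth component blobs. Class membership acts through an
#' amplitude shift on a chosen subset of components, so the discriminative
#' structure is fully known and downstream training, transfer and
#' cross-validation can be validated without gated clinical data.
#'
#' Per-participant component amplitudes are drawn from
#' `Normal(1, amplitude_sd)`; case-class participants get `effect_size`
#' added on the affected components. Amplitudes are keyed by the
#' within-class participant index, so a case and a control with the same
#' index share their baseline amplitudes (a matched-pairs phantom design:
#' with `effect_size = 0` and `noise_sd = 0` the two classes are
#' voxel-for-voxel identical).
#'
#' @param grid_size voxels per axis (>= 8), default 61.
#' @param n_channels number of network channels, default 8.
#' @param n_components_per_channel components (blobs) per channel, default 7.
#' @param n_per_group participants per class (>= 2).
#' @param effect_size amplitude shift applied to affected components in the
#'   case class (dimensionless, relative to the unit baseline amplitude).
#' @param shared_fraction fraction in `[0, 1]` of affected components shared
#'   between the source and target tasks (used by
#'   [generate_transfer_pair()]).
#' @param noise_sd standard deviation of additive voxel-wise Gaussian noise.
#' @param smoothing_sigma Gaussian blob width in voxels.
#' @param amplitude_sd within-class amplitude standard deviation.
#' @param seed integer seed; every random sub-stream (atlas, amplitudes,
#'   noise, affected-set choice) is derived from it by name.
#' @return an object of class `synthetic_spec`.
#' @export
#' @examples
#' spec <- synthetic_spec(grid_size = 16, n_channels = 2,
#'                        n_components_per_channel = 3, n_per_group = 4,
#'                        seed = 7)
synthetic_spec <- function(grid_size = 61, n_channels = 8,
                           n_components_per_channel = 7, n_per_group = 32,
                           effect_size = 1, shared_fraction = 1,
                           noise_sd = 0.5, smoothing_sigma = 2,
                           amplitude_sd = 0.1, seed = 1) {
  stop_if_not(grid_size >= 8, "synthetic_spec: grid_size must be >= 8")
  stop_if_not(n_per_group >= 2, "synthetic_spec: n_per_group must be >= 2")
  stop_if_not(shared_fraction >= 0 && shared_fraction <= 1,
              "synthetic_spec: shared_fraction must lie in [0, 1]")
  stop_if_not(noise_sd >= 0, "synthetic_spec: noise_sd must be >= 0")
  stop_if_not(is.finite(effect_size),
              "synthetic_spec: effect_size must be finite")
  stop_if_not(n_channels >= 1 && n_components_per_channel >= 1,
              "synthetic_spec: need at least one channel and component")
  structure(list(grid_size = as.integer(grid_size),
                 n_channels = as.integer(n_channels),
                 n_components_per_channel =
                   as.integer(n_components_per_channel),
                 n_per_group = as.integer(n_per_group),
                 effect_size = effect_size,
                 shared_fraction = shared_fraction,
                 noise_sd = noise_sd, smoothing_sigma = smoothing_sigma,
                 amplitude_sd = amplitude_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Build the component atlas for a synthetic cohort
#'
#' Places `n_components_per_channel` isotropic Gaussian blobs per channel at
#' uniformly sampled integer centers, with rejection sampling keeping
#' centers within a channel at least 4 voxels apart. Each component map is
#' non-negative and peak-normalized to 1. Components are indexed globally:
#' component `j` of channel `c` has index
#' `(c - 1) * n_components_per_channel + j`.
#'
#' @param spec a [synthetic_spec()].
#' @return an object of class `component_atlas` with fields `maps` (list of
#'   3D arrays, one per global component index), `centers`, `channel` and
#'   the originating spec.
#' @export
make_component_atlas <- function(spec) {
  stop_if_not(inherits(spec, "synthetic_spec"),
              "make_component_atlas: expected a synthetic_spec")
  g <- spec$grid_size
  k <- spec$n_components_per_channel
  min_sep2 <- 4^2
  ax <- seq_len(g)
  centers <- matrix(NA_real_, nrow = spec$n_channels * k, ncol = 3)
  channel <- rep(seq_len(spec$n_channels), each = k)
  with_seed(derive_seed(spec$seed, "atlas"), {
    for (c in seq_len(spec$n_channels)) {
      placed <- matrix(numeric(0), ncol = 3)
      tries <- 0
      while (nrow(placed) < k) {
        cand <- sample.int(g, 3, replace = TRUE)
        ok <- nrow(placed) == 0 ||
          all(colSums((t(placed) - cand)^2) >= min_sep2)
        if (ok) placed <- rbind(placed, cand)
        tries <- tries + 1
        if (tries > 2000 * k)
          stop(sprintf("make_component_atlas: cannot place %d components at least 4 voxels apart on a %d^3 grid",
                       k, g), call. = FALSE)
      }
      centers[channel == c, ] <- placed
    }
  })
  s2 <- 2 * spec$smoothing_sigma^2
  maps <- lapply(seq_len(nrow(centers)), function(i) {
    ctr <- centers[i, ]
    d2 <- outer(outer((ax - ctr[1])^2, (ax - ctr[2])^2, "+"),
                (ax - ctr[3])^2, "+")
    exp(-d2 / s2)
  })
  structure(list(maps = maps, centers = centers, channel = channel,
                 spec = spec),
            class = "component_atlas")
}

#' @export
print.component_atlas <- function(x, ...) {
  cat(sprintf("<component_atlas  %d channels x %d components on a %d^3 grid>\n",
              x$spec$n_channels, x$spec$n_components_per_channel,
              x$spec$grid_size))
  invisible(x)
}

#' Generate one synthetic cohort
#'
#' Each participant volume is the per-channel sum of the atlas component
#' maps weighted by that participant's amplitudes, plus voxel-wise
#' `Normal(0, noise_sd)` noise. Case-class amplitudes on the affected
#' components are shifted by `effect_size`. Classes are balanced:
#' `n_per_group` controls (label 0) and `n_per_group` cases (label 1).
#'
#' @param spec a [synthetic_spec()].
#' @param atlas a [make_component_atlas()] atlas built from a spec with the
#'   same grid and channel dimensions.
#' @param affected_components global component indices carrying the class
#'   effect; empty with nonzero `effect_size` triggers a warning (no
#'   discriminative signal will exist).
#' @param id_prefix prefix for participant identifiers.
#' @return an object of class `synthetic_cohort`: a list with `samples`
#'   (list of [volume_sample()]), `labels` (data frame
#'   `participant_id,label`), `affected_components` and `spec`.
#' @export
generate_cohort <- function(spec, atlas, affected_components,
                            id_prefix = "sub") {
  stop_if_not(inherits(spec, "synthetic_spec"),
              "generate_cohort: expected a synthetic_spec")
  stop_if_not(inherits(atlas, "component_atlas"),
              "generate_cohort: expected a component_atlas")
  stop_if_not(atlas$spec$grid_size == spec$grid_size &&
                atlas$spec$n_channels == spec$n_channels &&
                atlas$spec$n_components_per_channel ==
                  spec$n_components_per_channel,
              "generate_cohort: atlas dimensions do not match spec")
  n_comp <- length(atlas$maps)
  affected_components <- as.integer(affected_components)
  stop_if_not(all(affected_components >= 1 &
                    affected_components <= n_comp),
              "generate_cohort: affected component indices out of range 1..%d",
              n_comp)
  if (!length(affected_components) && spec$effect_size != 0)
    warning("generate_cohort: empty affected set with nonzero effect_size; cohort carries no discriminative signal",
            call. = FALSE)
  g <- spec$grid_size
  nv <- g^3
  # per channel: voxels x components matrix of atlas maps
  chan_mat <- lapply(seq_len(spec$n_channels), function(c)
    vapply(atlas$maps[atlas$channel == c], as.numeric, numeric(nv)))
  n <- 2L * spec$n_per_group
  samples <- vector("list", n)
  ids <- sprintf("%s-%03d", id_prefix, seq_len(n))
  labels <- rep(c(0L, 1L), each = spec$n_per_group)
  within_idx <- rep(seq_len(spec$n_per_group), times = 2)
  for (i in seq_len(n)) {
    amps <- with_seed(derive_seed(spec$seed, "amp", within_idx[i]),
                      rnorm(n_comp, mean = 1, sd = spec$amplitude_sd))
    if (labels[i] == 1L)
      amps[affected_components] <- amps[affected_components] +
        spec$effect_size
    vol <- array(0, c(spec$n_channels, g, g, g))
    for (c in seq_len(spec$n_channels)) {
      v <- chan_mat[[c]] %*% amps[atlas$channel == c]
      vol[c, , , ] <- v
    }
    if (spec$noise_sd > 0) {
      noise <- with_seed(derive_seed(spec$seed, "noise", labels[i],
                                     within_idx[i]),
                         rnorm(length(vol), 0, spec$noise_sd))
      vol <- vol + noise
    }
    samples[[i]] <- volume_sample(vol, ids[i], labels[i])
  }
  structure(list(samples = samples,
                 labels = data.frame(participant_id = ids, label = labels,
                                     stringsAsFactors = FALSE),
                 affected_components = affected_components,
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort  n = %d (%d per class), %d channels, %d^3 voxels, effect = %g>\n",
              nrow(x$labels), x$spec$n_per_group, x$spec$n_channels,
              x$spec$grid_size, x$spec$effect_size))
  invisible(x)
}

#' Generate a source/target cohort pair for transfer experiments
#'
#' Builds one atlas (from the source spec) and two cohorts on it whose
#' affected-component sets overlap in exactly
#' `round(shared_fraction * n_affected)` components, emulating a source
#' task and a target task that share part of their discriminative
#' structure. Both specs must agree on grid size and channel count.
#'
#' @param source_spec,target_spec [synthetic_spec()] objects.
#' @param shared_fraction overlap fraction; defaults to the target spec's.
#' @param n_affected number of affected components per task (default: half
#'   of all components, rounded down).
#' @return an object of class `transfer_pair`: list with `source`,
#'   `target` (both [generate_cohort()] results), `atlas` and `provenance`
#'   (both affected sets, all seeds, the realized overlap).
#' @export
generate_transfer_pair <- function(source_spec, target_spec,
                                   shared_fraction =
                                     target_spec$shared_fraction,
                                   n_affected = NULL) {
  stop_if_not(inherits(source_spec, "synthetic_spec") &&
                inherits(target_spec, "synthetic_spec"),
              "generate_transfer_pair: expected two synthetic_spec objects")
  stop_if_not(source_spec$grid_size == target_spec$grid_size &&
                source_spec$n_channels == target_spec$n_channels &&
                source_spec$n_components_per_channel ==
                  target_spec$n_components_per_channel,
              "generate_transfer_pair: source and target specs must share grid_size and channel dimensions")
  stop_if_not(shared_fraction >= 0 && shared_fraction <= 1,
              "generate_transfer_pair: shared_fraction must lie in [0, 1]")
  atlas <- make_component_atlas(source_spec)
  n_comp <- length(atlas$maps)
  if (is.null(n_affected)) n_affected <- n_comp %/% 2
  n_shared <- round(shared_fraction * n_affected)
  stop_if_not(2 * n_affected - n_shared <= n_comp,
              "generate_transfer_pair: not enough components (%d) for two affected sets of %d sharing %d",
              n_comp, n_affected, n_shared)
  src_set <- with_seed(derive_seed(source_spec$seed, "affected"),
                       sort(sample.int(n_comp, n_affected)))
  tgt_set <- with_seed(derive_seed(target_spec$seed, "affected", "target"), {
    shared <- if (n_shared > 0) {
      sample(src_set, n_shared)
    } else integer(0)
    pool <- setdiff(seq_len(n_comp), src_set)
    fresh <- if (n_affected - n_shared > 0) {
      sample(pool, n_affected - n_shared)
    } else integer(0)
    sort(c(shared, fresh))
  })
  source <- generate_cohort(source_spec, atlas, src_set, id_prefix = "src")
  target <- generate_cohort(target_spec, atlas, tgt_set, id_prefix = "tgt")
  structure(list(source = source, target = target, atlas = atlas,
                 provenance = list(
                   source_affected = src_set, target_affected = tgt_set,
                   overlap = intersect(src_set, tgt_set),
                   n_affected = n_affected,
                   shared_fraction = shared_fraction,
                   source_seed = source_spec$seed,
                   target_seed = target_spec$seed)),
            class = "transfer_pair")
}

#' Export a cohort as NIfTI volumes plus a label sheet
#'
#' Writes one 4D NIfTI (`X x Y x Z x channels`, float32) per participant,
#' a `labels.csv` with columns `participant_id,label,split`, and a
#' `provenance.json` recording the generating spec and affected components.
#' Volumes round-trip through [load_volume()] at float32 precision.
#'
#' @param cohort a [generate_cohort()] result.
#' @param directory output directory (created if missing).
#' @param split optional character vector of split assignments per
#'   participant (stored in the label sheet).
#' @return invisibly, the paths of the written volume files.
#' @export
export_cohort <- function(cohort, directory, split = NA_character_) {
  stop_if_not(inherits(cohort, "synthetic_cohort"),
              "export_cohort: expected a synthetic_cohort")
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  stop_if_not(dir.exists(directory),
              "export_cohort: cannot create directory %s", directory)
  paths <- vapply(cohort$samples, function(s) {
    path <- file.path(directory, paste0(s$participant_id, ".nii.gz"))
    ok <- tryCatch({
      RNifti::writeNifti(aperm(s$data, c(2, 3, 4, 1)), path,
                         datatype = "float")
      TRUE
    }, error = function(e) {
      stop(sprintf("export_cohort: failed writing %s: %s", path,
                   conditionMessage(e)), call. = FALSE)
    })
    path
  }, character(1))
  sheet <- cohort$labels
  sheet$split <- split
  write.csv(sheet, file.path(directory, "labels.csv"), row.names = FALSE)
  prov <- c(unclass(cohort$spec),
            list(affected_components = cohort$affected_components))
  jsonlite::write_json(prov, file.path(directory, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Load a cohort previously written by [export_cohort()]
#'
#' @param directory directory containing the NIfTI files and `labels.csv`.
#' @return a list with `samples` and `labels`, compatible with the
#'   in-memory cohort layout.
#' @export
load_cohort <- function(directory) {
  sheet_path <- file.path(directory, "labels.csv")
  stop_if_not(file.exists(sheet_path),
              "load_cohort: no labels.csv under %s", directory)
  sheet <- read.csv(sheet_path, stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(sheet)), function(i)
    load_volume(file.path(directory,
                          paste0(sheet$participant_id[i], ".nii.gz")),
                label = sheet$label[i],
                participant_id = sheet$participant_id[i]))
  structure(list(samples = samples, labels = sheet),
            class = "synthetic_cohort")
}
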