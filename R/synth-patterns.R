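#' Generate beta-like voxel patterns for every subject
#'
#' Simulates per-stimulus, per-run pattern estimates with spatially localized
#' category signal. In each informative region the two classes of the region's
#' dimension are shifted apart by `signal_sd` per voxel; each exemplar
#' additionally carries a fixed offset along that same discriminant direction
#' (drawn once per subject, constant across runs), which creates the
#' exemplar-level boundary-distance variation the distance-to-bound analysis
#' targets. I.i.d. Gaussian noise of SD `run_noise_sd` is added per
#' stimulus x sample x voxel. Everything is a pure function of the config seed.
#'
#' The true (noise-free) correct-side distance of stimulus `j` from the
#' dimension-`k` boundary is `1 + o_jk` in boundary units, where
#' `o_jk ~ N(0, exemplar_offset_sd)`; values below 0 put the exemplar on the
#' wrong side of its own boundary.
#'
#' @param design A design tibble from [generate_design()].
#' @param config An [synth_config()] object.
#' @return An object of class `ndba_pattern_set`: a list with elements
#'   `subjects` (list of `ndba_patterns`, each holding `values`
#'   `[stimulus x sample x voxel]`, `sample_info`, `true_distances`),
#'   `design`, `voxel_coords`, and `config`.
#' @export
generate_patterns <- function(design, config = synth_config()) {
  validate_synth_config(config)
  S <- nrow(design)
  n_samples <- config$n_runs_per_task * config$n_repeats_per_run
  V <- config$n_voxels
  coords <- voxel_grid(config$grid_dims)
  sample_info <- tibble::tibble(
    sample = seq_len(n_samples),
    run = rep(seq_len(config$n_runs_per_task), each = config$n_repeats_per_run),
    rep = rep(seq_len(config$n_repeats_per_run), times = config$n_runs_per_task)
  )
  dimensions <- unique(unlist(lapply(config$signal_sd, names)))

  subjects <- lapply(seq_len(config$n_subjects), function(s) {
    with_substream(config$seed, "patterns", s, code = {
      # Per-subject exemplar offsets per dimension (boundary units).
      offsets <- matrix(rnorm(S * length(dimensions), 0, config$exemplar_offset_sd),
                        nrow = S, ncol = length(dimensions),
                        dimnames = list(NULL, dimensions))
      true_d <- tidyr::expand_grid(stimulus_id = design$stimulus_id,
                                   dimension = dimensions) |>
        dplyr::mutate(distance = 1 + offsets[cbind(
          match(.data$stimulus_id, design$stimulus_id),
          match(.data$dimension, dimensions))])

      mean_map <- matrix(0, nrow = S, ncol = V)
      for (r in names(config$region_layout)) {
        vox <- config$region_layout[[r]]
        sds <- config$signal_sd[[r]]
        for (k in names(sds)) {
          if (sds[[k]] <= 0) next
          lab <- task_labels(design, if (k == "animacy") "animacy" else "shape")
          side <- ifelse(as.integer(lab) == 1L, 1, -1)  # first level positive
          amp <- side * sds[[k]] * (1 + offsets[, k])
          mean_map[, vox] <- mean_map[, vox] + amp
        }
      }
      values <- array(rnorm(S * n_samples * V, 0, config$run_noise_sd),
                      dim = c(S, n_samples, V))
      for (i in seq_len(n_samples)) values[, i, ] <- values[, i, ] + mean_map
      structure(list(subject_id = sprintf("sub-%02d", s),
                     values = values,
                     stimulus_id = design$stimulus_id,
                     sample_info = sample_info,
                     true_distances = true_d),
                class = "ndba_patterns")
    })
  })

  structure(list(subjects = subjects, design = design,
                 voxel_coords = coords, config = config),
            class = "ndba_pattern_set")
}

#' @export
print.ndba_pattern_set <- function(x, ...) {
  d <- dim(x$subjects[[1]]$values)
  cat(sprintf("<ndba_pattern_set> %d subjects, %d stimuli x %d samples x %d voxels\n",
              length(x$subjects), d[1], d[2], d[3]))
  invisible(x)
}

#' True stimulus distances planted by the generator
#'
#' @param patterns An `ndba_pattern_set`.
#' @return A tibble `(subject_id, stimulus_id, dimension, distance)` of the
#'   noise-free correct-side boundary distances (boundary units).
#' @export
true_distances <- function(patterns) {
  purrr::map_dfr(patterns$subjects, function(p) {
    dplyr::mutate(p$true_distances, subject_id = p$subject_id, .before = 1)
  })
}

#' Per-task driving distances for the behavior generator
#'
#' The animacy and shape tasks are driven by the absolute true distance from
#' their own boundary. The crisscross (indoor/outdoor) task, which is not
#' linearly separable along either dimension, is driven by the mean of the two
#' absolute distances -- a scaled city-block combination of the planted
#' dimensions.
#'
#' @param patterns An `ndba_pattern_set`.
#' @param tasks Tasks to include.
#' @return A tibble `(subject_id, task, stimulus_id, distance)` with
#'   `distance >= 0`.
#' @export
behavior_true_distances <- function(patterns, tasks = ndba_tasks()) {
  td <- true_distances(patterns) |>
    tidyr::pivot_wider(names_from = "dimension", values_from = "distance")
  purrr::map_dfr(tasks, function(tk) {
    d <- switch(tk,
      animacy = abs(td$animacy),
      shape = abs(td$shape),
      indoor_outdoor = (abs(td$animacy) + abs(td$shape)) / 2)
    tibble::tibble(subject_id = td$subject_id, task = tk,
                   stimulus_id = td$stimulus_id, distance = d)
  })
}

# Flatten one subject's patterns into a samples x voxels matrix plus
# per-sample stimulus/run bookkeeping.
flatten_patterns <- function(subject, voxels = NULL) {
  d <- dim(subject$values)
  S <- d[1]; n_samples <- d[2]
  vox <- if (is.null(voxels)) seq_len(d[3]) else voxels
  x <- matrix(aperm(subject$values[, , vox, drop = FALSE], c(2, 1, 3)),
              nrow = S * n_samples, ncol = length(vox))
  info <- tibble::tibble(
    stimulus = rep(seq_len(S), each = n_samples),
    sample = rep(subject$sample_info$sample, times = S),
    run = rep(subject$sample_info$run, times = S)
  )
  list(x = x, info = info)
}
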