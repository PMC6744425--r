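#' Write and read pattern datasets as NIfTI volumes
#'
#' One 3-D volume per stimulus x sample, stacked along the fourth axis, plus a
#' JSON sidecar holding the subject id, design labels, sample bookkeeping, and
#' voxel coordinates so the dataset round-trips exactly.
#'
#' @param subject An `ndba_patterns` object.
#' @param design The design tibble.
#' @param voxel_coords Integer `[voxel x 3]` grid coordinates.
#' @param grid_dims Grid dimensions of the volume.
#' @param path Output path without extension; writes `<path>.nii.gz` and
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_patterns_nifti <- function(subject, design, voxel_coords, grid_dims, path) {
  d <- dim(subject$values)
  vol <- array(0, dim = c(grid_dims, d[1] * d[2]))
  idx <- cbind(voxel_coords[rep(seq_len(nrow(voxel_coords)), times = d[1] * d[2]), ],
               rep(seq_len(d[1] * d[2]), each = nrow(voxel_coords)))
  # volume t = (stimulus i, sample j) with sample varying fastest
  flat <- matrix(aperm(subject$values, c(3, 2, 1)), nrow = d[3])
  vol[idx] <- as.vector(flat)
  RNifti::writeNifti(RNifti::asNifti(vol), paste0(path, ".nii.gz"))
  sidecar <- list(subject_id = subject$subject_id,
                  n_stimuli = d[1], n_samples = d[2],
                  stimulus_id = subject$stimulus_id,
                  sample_info = subject$sample_info,
                  voxel_coords = voxel_coords,
                  design = design,
                  true_distances = subject$true_distances)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_patterns_nifti
#' @return For the reader: a list with the reconstructed `ndba_patterns`
#'   object, the `design` tibble, and `voxel_coords`.
#' @export
read_patterns_nifti <- function(path) {
  vol <- RNifti::readNifti(paste0(path, ".nii.gz"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  coords <- as.matrix(side$voxel_coords)
  S <- side$n_stimuli; n_samples <- side$n_samples
  v <- nrow(coords)
  flat <- matrix(0, nrow = v, ncol = S * n_samples)
  for (t in seq_len(S * n_samples)) {
    flat[, t] <- vol[cbind(coords, t)]
  }
  values <- aperm(array(flat, dim = c(v, n_samples, S)), c(3, 2, 1))
  design <- tibble::as_tibble(side$design)
  for (col in c("cluster", "animacy", "shape", "crisscross")) {
    design[[col]] <- factor(design[[col]], levels = unique(side$design[[col]]))
  }
  subject <- structure(list(
    subject_id = side$subject_id,
    values = values,
    stimulus_id = as.integer(side$stimulus_id),
    sample_info = tibble::as_tibble(side$sample_info),
    true_distances = tibble::as_tibble(side$true_distances)
  ), class = "ndba_patterns")
  list(subject = subject, design = design, voxel_coords = coords)
}

#' Behavior CSV round trip
#'
#' Schema: `subject_id, task, run, rep, stimulus_id, rt_ms, correct`.
#'
#' @param trials Trial tibble.
#' @param path CSV path.
#' @export
write_behavior_csv <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname write_behavior_csv
#' @export
read_behavior_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("subject_id", "task", "run", "stimulus_id", "rt_ms", "correct")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    ndba_abort(paste0("Behavior CSV missing column(s): ",
                      paste(missing, collapse = ", ")), "ndba_invalid_input")
  }
  x$correct <- as.logical(x$correct)
  x
}

#' Design JSON round trip
#'
#' @param design Design tibble.
#' @param path JSON path.
#' @export
write_design_json <- function(design, path) {
  jsonlite::write_json(design, path, dataframe = "columns", factor = "string",
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_design_json
#' @export
read_design_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tibble::tibble(
    stimulus_id = as.integer(x$stimulus_id),
    cluster = factor(x$cluster, levels = ndba_clusters()),
    animacy = factor(x$animacy, levels = c("animate", "inanimate")),
    shape = factor(x$shape, levels = c("bar", "blob")),
    crisscross = factor(x$crisscross, levels = c("indoor", "outdoor"))
  )
}

#' Write stimulus images as PNG
#'
#' @param images Named list of matrices in `[0, 1]` (from [generate_images()]).
#' @param dir Output directory.
#' @return The written file paths, invisibly.
#' @export
write_images_png <- function(images, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(images), function(id) {
    p <- file.path(dir, sprintf("stimulus_%s.png", id))
    png::writePNG(images[[id]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Read/write a run configuration as YAML
#'
#' Serializes the analysis knobs and the synthetic-generator settings
#' (region layout as voxel index vectors) so a run is reproducible from a
#' plain-text file.
#'
#' @param config An [ndba_config()].
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$synth <- unclass(x$synth)
  x$synth$signal_sd <- lapply(x$synth$signal_sd, as.list)
  x$synth$asymmetry <- lapply(x$synth$asymmetry, as.list)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  s <- x$synth
  synth <- synth_config(
    n_subjects = s$n_subjects, n_runs_per_task = s$n_runs_per_task,
    n_repeats_per_run = s$n_repeats_per_run, grid_dims = unlist(s$grid_dims),
    region_layout = lapply(s$region_layout, unlist),
    signal_sd = lapply(s$signal_sd, unlist),
    exemplar_offset_sd = s$exemplar_offset_sd, run_noise_sd = s$run_noise_sd,
    rt_intercept_ms = s$rt_intercept_ms,
    rt_slope_ms_per_distance = s$rt_slope_ms_per_distance,
    rt_noise_sd_ms = s$rt_noise_sd_ms,
    asymmetry = lapply(s$asymmetry, unlist),
    accuracy_base = s$accuracy_base,
    accuracy_link_scale = s$accuracy_link_scale,
    bar_clusters = unlist(s$bar_clusters), seed = s$seed)
  ndba_config(synth = synth, k_neighborhood = x$k_neighborhood,
              q_threshold = x$q_threshold, top_fraction = x$top_fraction,
              k_folds = x$k_folds, n_splits = x$n_splits,
              shrinkage = if (identical(x$shrinkage, "lw")) "lw" else x$shrinkage,
              rt_basis = x$rt_basis, exclusion_alpha = x$exclusion_alpha,
              run_gist = x$run_gist, image_size = x$image_size, seed = x$seed)
}
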