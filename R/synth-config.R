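#' Voxel grid coordinates
#'
#' Integer (x, y, z) coordinates for every voxel of a rectangular grid, in
#' x-fastest order (matching R array linearization).
#'
#' @param grid_dims Integer vector of length 3.
#' @return An integer matrix `[n_voxels x 3]` with columns `x`, `y`, `z`.
#' @export
voxel_grid <- function(grid_dims) {
  stopifnot(length(grid_dims) == 3, all(grid_dims >= 1))
  coords <- arrayInd(seq_len(prod(grid_dims)), .dim = as.integer(grid_dims))
  colnames(coords) <- c("x", "y", "z")
  coords
}

#' Voxel indices of a rectangular block
#'
#' @param grid_dims Integer vector of length 3.
#' @param x,y,z Integer ranges of the block along each axis.
#' @return Integer voxel indices into the grid of [voxel_grid()].
#' @export
block_indices <- function(grid_dims, x, y, z) {
  coords <- voxel_grid(grid_dims)
  which(coords[, 1] %in% x & coords[, 2] %in% y & coords[, 3] %in% z)
}

# Default informative-region layout for the default 28 x 9 x 8 grid: two
# disjoint 150-voxel blocks (10 x 5 x 3), each flush against one z-face of the
# grid (so no out-of-block layer can capture a more block-heavy neighborhood
# than the block interior itself), centered in y, with a genuine background
# region (x >= 20) more than two neighborhood radii from both blocks.
default_region_layout <- function(grid_dims) {
  list(
    loc_like = block_indices(grid_dims, x = 4:13, y = 3:7, z = 1:3),
    evc_like = block_indices(grid_dims, x = 4:13, y = 3:7, z = 6:8)
  )
}

#' Configuration for the synthetic-data generator
#'
#' Bundles the study-design counts, the planted spatial signal layout, and the
#' behavioral coupling parameters. The defaults define the simulated study
#' conditions: 8 subjects, 3 runs per task with 2 pattern repeats per run over
#' 32 stimuli, a 28 x 9 x 8 voxel grid (2016 voxels) with two disjoint
#' 150-voxel informative blocks -- a "LOC-like" block carrying animacy signal
#' and an "EVC-like" block carrying shape signal -- and reaction times
#' negatively coupled to the true decision-boundary distance, with the
#' coupling confined (or attenuated) per category via `asymmetry`.
#'
#' @param n_subjects Number of simulated subjects.
#' @param n_runs_per_task Runs per task (the same true patterns serve all tasks).
#' @param n_repeats_per_run Pattern estimates per stimulus per run.
#' @param grid_dims Voxel grid dimensions (x, y, z).
#' @param region_layout Named list of disjoint voxel index sets; remaining
#'   voxels are uninformative background.
#' @param signal_sd Named list mapping region name to a named numeric of
#'   per-voxel class-mean shifts per dimension, e.g.
#'   `list(loc_like = c(animacy = 0.2))`. Units: multiples of `run_noise_sd`.
#' @param exemplar_offset_sd SD of the per-exemplar offset along the planted
#'   discriminant direction, in units of the category boundary distance; this
#'   is the single planted driver of stimulus-level RT variation. Offsets are
#'   drawn per subject.
#' @param run_noise_sd SD of i.i.d. Gaussian measurement noise per pattern value.
#' @param rt_intercept_ms,rt_slope_ms_per_distance,rt_noise_sd_ms Linear RT
#'   model: `RT = intercept + slope * asymmetry * |true distance| + noise`,
#'   truncated below at 150 ms. The slope is negative for the planted effect.
#' @param asymmetry Named list per task of category -> coupling multiplier in
#'   `[0, 1]`, applied to the effective distance driving both RT and accuracy.
#'   Defaults plant the full effect for animate, a graded effect for blob vs
#'   bar, and an indoor-only effect for the crisscross task.
#' @param accuracy_base Baseline distance offset (boundary units) in the
#'   accuracy link; sets the floor accuracy an uncoupled category keeps
#'   (`plogis(base / scale)`, about 0.88 at the defaults).
#' @param accuracy_link_scale Scale of the logistic accuracy link
#'   `p(correct) = plogis((base + m * |true distance|) / scale)` (always
#'   above 0.5). `0` is the deterministic limit: every response correct.
#' @param bar_clusters Passed to [generate_design()].
#' @param seed Integer root seed for the generator substreams.
#' @return A validated list of class `ndba_synth_config`.
#' @export
synth_config <- function(n_subjects = 8,
                         n_runs_per_task = 3,
                         n_repeats_per_run = 2,
                         grid_dims = c(28, 9, 8),
                         region_layout = NULL,
                         signal_sd = list(loc_like = c(animacy = 0.2),
                                          evc_like = c(shape = 0.2)),
                         exemplar_offset_sd = 0.7,
                         run_noise_sd = 1,
                         rt_intercept_ms = 900,
                         rt_slope_ms_per_distance = -250,
                         rt_noise_sd_ms = 80,
                         asymmetry = list(
                           animacy = c(animate = 1, inanimate = 0),
                           shape = c(blob = 1, bar = 0.5),
                           indoor_outdoor = c(indoor = 1, outdoor = 0)),
                         accuracy_base = 1,
                         accuracy_link_scale = 0.5,
                         bar_clusters = c("insects", "tools"),
                         seed = 1L) {
  if (is.null(region_layout)) {
    if (!identical(as.integer(grid_dims), c(28L, 9L, 8L))) {
      ndba_abort("Supply `region_layout` explicitly for non-default `grid_dims`.",
                 "ndba_invalid_argument")
    }
    region_layout <- default_region_layout(grid_dims)
  }
  n_voxels <- prod(grid_dims)
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_runs_per_task = as.integer(n_runs_per_task),
    n_repeats_per_run = as.integer(n_repeats_per_run),
    grid_dims = as.integer(grid_dims),
    n_voxels = as.integer(n_voxels),
    region_layout = lapply(region_layout, as.integer),
    signal_sd = signal_sd,
    exemplar_offset_sd = exemplar_offset_sd,
    run_noise_sd = run_noise_sd,
    rt_intercept_ms = rt_intercept_ms,
    rt_slope_ms_per_distance = rt_slope_ms_per_distance,
    rt_noise_sd_ms = rt_noise_sd_ms,
    asymmetry = asymmetry,
    accuracy_base = accuracy_base,
    accuracy_link_scale = accuracy_link_scale,
    bar_clusters = bar_clusters,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "ndba_synth_config")
}

validate_synth_config <- function(cfg) {
  with(cfg, {
    if (n_subjects < 1 || n_runs_per_task < 1 || n_repeats_per_run < 1) {
      ndba_abort("Design counts must all be >= 1.", "ndba_invalid_argument")
    }
    if (run_noise_sd <= 0) {
      ndba_abort("`run_noise_sd` must be positive.", "ndba_invalid_argument")
    }
    if (exemplar_offset_sd < 0 || accuracy_link_scale < 0 || accuracy_base < 0 ||
        rt_noise_sd_ms <= 0 || rt_intercept_ms <= 0) {
      ndba_abort("Noise/scale parameters must be nonnegative (RT intercept/noise positive).",
                 "ndba_invalid_argument")
    }
    all_region <- unlist(region_layout, use.names = FALSE)
    if (anyDuplicated(all_region)) {
      ndba_abort("Region voxel index sets must be disjoint.", "ndba_invalid_argument")
    }
    if (length(all_region) > 0 && (max(all_region) > n_voxels || min(all_region) < 1)) {
      ndba_abort("Region voxel indices must lie within the grid.", "ndba_invalid_argument")
    }
    has_signal <- any(unlist(signal_sd) > 0)
    if (has_signal && length(all_region) == 0) {
      ndba_abort("Nonzero `signal_sd` requires a nonempty region layout.",
                 "ndba_invalid_argument")
    }
    bad_sd <- any(vapply(signal_sd, function(x) any(x < 0), logical(1)))
    if (bad_sd) ndba_abort("`signal_sd` entries must be >= 0.", "ndba_invalid_argument")
    for (tk in names(asymmetry)) {
      if (any(asymmetry[[tk]] < 0 | asymmetry[[tk]] > 1)) {
        ndba_abort("`asymmetry` multipliers must lie in [0, 1].", "ndba_invalid_argument")
      }
    }
    unknown <- setdiff(names(signal_sd), names(region_layout))
    if (length(unknown) > 0) {
      ndba_abort(paste0("`signal_sd` names not in region layout: ",
                        paste(unknown, collapse = ", ")), "ndba_invalid_argument")
    }
    invisible(NULL)
  })
  invisible(cfg)
}

#' @export
print.ndba_synth_config <- function(x, ...) {
  cat("<ndba_synth_config>\n")
  cat(sprintf("  %d subjects, %d runs/task x %d repeats, %d voxels (grid %s)\n",
              x$n_subjects, x$n_runs_per_task, x$n_repeats_per_run, x$n_voxels,
              paste(x$grid_dims, collapse = "x")))
  for (r in names(x$region_layout)) {
    sds <- x$signal_sd[[r]]
    cat(sprintf("  region %-9s %4d voxels  signal: %s\n", r,
                length(x$region_layout[[r]]),
                if (is.null(sds)) "none" else
                  paste(names(sds), signif(sds, 3), sep = "=", collapse = ", ")))
  }
  cat(sprintf("  RT: %g %+g*|d| (noise %g ms), accuracy scale %g, seed %d\n",
              x$rt_intercept_ms, x$rt_slope_ms_per_distance, x$rt_noise_sd_ms,
              x$accuracy_link_scale, x$seed))
  invisible(x)
}
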