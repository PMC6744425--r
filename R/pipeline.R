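#' Pipeline run configuration
#'
#' Bundles the synthetic-data config with the analysis knobs. The defaults
#' reproduce the standard analysis settings: 100-voxel neighborhoods,
#' FDR-adjusted p threshold 0.005, top 10% voxel selection, 5-fold (4/5)
#' train-test distances, 100 reliability splits, Ledoit-Wolf shrinkage, and
#' correct-only RT basis.
#'
#' @param synth An [synth_config()] object (synthetic mode).
#' @param k_neighborhood Searchlight neighborhood size.
#' @param q_threshold FDR-adjusted p threshold for the significance mask.
#' @param top_fraction Fraction of significant voxels kept as the ROI.
#' @param k_folds Folds for the distance cross-validation.
#' @param n_splits Reliability splits.
#' @param shrinkage LDA shrinkage (`"lw"` or fixed value).
#' @param rt_basis `"correct_only"` or `"all"`.
#' @param exclusion_alpha Level of the at-chance subject exclusion test.
#' @param run_gist Run the image-descriptor control analysis.
#' @param image_size Synthetic stimulus image side (pixels).
#' @param seed Root seed; stage substreams are derived from it.
#' @return A list of class `ndba_config`.
#' @export
ndba_config <- function(synth = synth_config(),
                        k_neighborhood = 100,
                        q_threshold = 0.005,
                        top_fraction = 0.10,
                        k_folds = 5,
                        n_splits = 100,
                        shrinkage = "lw",
                        rt_basis = "correct_only",
                        exclusion_alpha = 0.05,
                        run_gist = TRUE,
                        image_size = 128,
                        seed = 1L) {
  problems <- character(0)
  if (!inherits(synth, "ndba_synth_config")) problems <- c(problems, "synth")
  if (k_neighborhood < 1) problems <- c(problems, "k_neighborhood")
  if (q_threshold <= 0 || q_threshold > 1) problems <- c(problems, "q_threshold")
  if (top_fraction <= 0 || top_fraction > 1) problems <- c(problems, "top_fraction")
  if (k_folds < 2) problems <- c(problems, "k_folds")
  if (n_splits < 1) problems <- c(problems, "n_splits")
  if (!identical(shrinkage, "lw") &&
      (!is.numeric(shrinkage) || shrinkage < 0 || shrinkage > 1)) {
    problems <- c(problems, "shrinkage")
  }
  if (!rt_basis %in% c("correct_only", "all")) problems <- c(problems, "rt_basis")
  if (length(problems) > 0) {
    ndba_abort(paste0("Invalid config field(s): ", paste(problems, collapse = ", ")),
               "ndba_invalid_config")
  }
  structure(list(synth = synth, k_neighborhood = as.integer(k_neighborhood),
                 q_threshold = q_threshold, top_fraction = top_fraction,
                 k_folds = as.integer(k_folds), n_splits = as.integer(n_splits),
                 shrinkage = shrinkage, rt_basis = rt_basis,
                 exclusion_alpha = exclusion_alpha,
                 run_gist = isTRUE(run_gist), image_size = as.integer(image_size),
                 seed = as.integer(seed)),
            class = "ndba_config")
}

#' Run the full distance-to-bound pipeline on synthetic data
#'
#' Stages: stimulus design and synthetic generation (patterns, behavior,
#' optionally images); GIST cross-decoding control; searchlight decoding per
#' dimension with group FDR inference and top-fraction ROI selection;
#' fold-averaged boundary distances per subject, ROI, and classifier
#' dimension (with the percentile-summed combination for the crisscross
#' task); behavior aggregation, at-chance exclusion, and LISAS scoring;
#' per-category distance-behavior correlation with group inference and the
#' category-asymmetry test; and split-half joint reliability per cell.
#' Failure of one ROI x task cell (e.g. an empty ROI) is recorded as a
#' warning in the report, not fatal. Fully deterministic given `config$seed`.
#'
#' @param config An [ndba_config()].
#' @param out_dir Optional directory; when given, summary and per-subject
#'   CSVs, the behavior table, searchlight maps, and a JSON run report are
#'   written there.
#' @param verbose Print stage progress.
#' @return An object of class `ndba_run`: list with `summary` (tibble: roi,
#'   task, category, n_subjects, mean_r, t, df, p, plus reliability columns),
#'   `results` (ndba_result objects), `searchlight`, `rois`, `gist`,
#'   `behavior`, `exclusions`, `warnings`, `config`.
#' @export
run_ndba_pipeline <- function(config = ndba_config(), out_dir = NULL,
                              verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  warnings_log <- character(0)
  note <- function(msg) warnings_log <<- c(warnings_log, msg)
  synth <- config$synth
  synth$seed <- substream_seed(config$seed, "synth")

  say("[1/7] generating design, patterns, behavior (%d subjects, %d voxels)",
      synth$n_subjects, synth$n_voxels)
  design <- generate_design(8, bar_clusters = synth$bar_clusters)
  patterns <- generate_patterns(design, synth)
  trials <- generate_behavior(design, behavior_true_distances(patterns), synth)

  gist_res <- NULL
  if (config$run_gist) {
    say("[2/7] image-descriptor (GIST) cross-decoding control")
    images <- generate_images(design, size = config$image_size,
                              seed = substream_seed(config$seed, "images"))
    desc <- gist_descriptors(images)
    gist_res <- purrr::map_dfr(c("animacy", "shape"), function(dm) {
      dplyr::mutate(crossdecode_descriptors(desc, design, dm), dimension = dm,
                    .before = 1)
    })
  } else say("[2/7] image control skipped")

  say("[3/7] behavior scoring and exclusions")
  excl <- exclude_chance_subjects(trials, alpha = config$exclusion_alpha)
  if (length(excl$excluded) > 0) {
    note(sprintf("Excluded at-chance subject(s): %s",
                 paste(excl$excluded, collapse = ", ")))
  }
  scores <- behavior_scores(trials, rt_basis = config$rt_basis)
  group_vectors <- lapply(setNames(nm = ndba_tasks()), function(tk) {
    group_behavior_vector(scores, tk, keep_subjects = excl$kept)
  })
  kept_idx <- which(vapply(patterns$subjects, function(p)
    p$subject_id %in% excl$kept, logical(1)))

  say("[4/7] searchlight decoding (k = %d) per dimension", config$k_neighborhood)
  nbhd <- build_neighborhoods(patterns$voxel_coords, k = config$k_neighborhood)
  dims <- c("animacy", "shape")
  searchlight <- lapply(setNames(nm = dims), function(dm) {
    labels <- task_labels(design, dm)
    maps <- do.call(rbind, lapply(patterns$subjects[kept_idx], run_searchlight,
                                  labels = labels, neighborhoods = nbhd,
                                  shrinkage = config$shrinkage))
    group <- group_significance(maps, q_threshold = config$q_threshold)
    list(maps = maps, group = group)
  })
  rois <- lapply(setNames(nm = dims), function(dm) {
    tryCatch(select_top_voxels(searchlight[[dm]]$group, patterns$voxel_coords,
                               fraction = config$top_fraction),
             ndba_empty_roi = function(e) {
               note(sprintf("No significant %s decoding: empty ROI, cells skipped.", dm))
               integer(0)
             })
  })

  say("[5/7] fold-averaged boundary distances per subject and ROI")
  # distances[[roi_dim]][[classifier_dim]][[subject]]
  distances <- lapply(setNames(nm = dims), function(roi_dim) {
    vox <- rois[[roi_dim]]
    if (length(vox) == 0) return(NULL)
    lapply(setNames(nm = dims), function(clf_dim) {
      labels <- task_labels(design, clf_dim)
      lapply(patterns$subjects[kept_idx], function(p) {
        crossval_distances(p, labels, voxels = vox, k = config$k_folds,
                           shrinkage = config$shrinkage,
                           seed = substream_seed(config$seed, "folds",
                                                 roi_dim, clf_dim, p$subject_id))
      })
    })
  })

  say("[6/7] distance-behavior correlation and reliability per cell")
  cells <- tidyr::expand_grid(roi = dims, task = ndba_tasks())
  results <- list()
  reliab <- list()
  for (i in seq_len(nrow(cells))) {
    roi_dim <- cells$roi[[i]]; tk <- cells$task[[i]]
    if (is.null(distances[[roi_dim]])) next
    key <- paste(roi_dim, tk, sep = ".")
    subj_ids <- vapply(patterns$subjects[kept_idx], `[[`, character(1), "subject_id")
    clf <- task_dimension(tk)
    dist_tbl <- purrr::map_dfr(seq_along(kept_idx), function(j) {
      if (!is.na(clf)) {
        d <- distances[[roi_dim]][[clf]][[j]]
        tibble::tibble(subject_id = subj_ids[j], stimulus_id = d$stimulus_id,
                       distance = d$distance)
      } else {
        da <- distances[[roi_dim]][["animacy"]][[j]]
        ds <- distances[[roi_dim]][["shape"]][[j]]
        tibble::tibble(subject_id = subj_ids[j], stimulus_id = da$stimulus_id,
                       distance = crisscross_distance(da$distance, ds$distance))
      }
    })
    res <- ndba_analysis(dist_tbl, group_vectors[[tk]], design, tk,
                         roi = paste0("roi_", roi_dim))
    results[[key]] <- res

    labels <- task_labels(design, tk)
    rel <- purrr::map_dfr(levels(labels), function(cat) {
      stim <- design$stimulus_id[labels == cat]
      rb <- behavior_split_half(trials, tk, stimuli = stim,
                                keep_subjects = excl$kept,
                                rt_basis = config$rt_basis,
                                n_splits = config$n_splits,
                                seed = substream_seed(config$seed, "rel-b", tk, cat))
      rn_subj <- vapply(seq_along(kept_idx), function(j) {
        dd <- if (!is.na(clf)) distances[[roi_dim]][[clf]][[j]]
              else list(distances[[roi_dim]][["animacy"]][[j]],
                        distances[[roi_dim]][["shape"]][[j]])
        as.numeric(neural_split_half(dd, stimuli = stim,
                                     n_splits = config$n_splits,
                                     seed = substream_seed(config$seed, "rel-n",
                                                           roi_dim, tk, cat, j)))
      }, numeric(1))
      dplyr::mutate(reliability_estimate(rb, mean(rn_subj)),
                    category = cat, .before = 1)
    })
    reliab[[key]] <- rel
  }

  say("[7/7] assembling report")
  summary <- purrr::imap_dfr(results, function(res, key) {
    rel <- reliab[[key]]
    res$summary |>
      dplyr::rename(n_subjects = "n") |>
      dplyr::left_join(rel[c("category", "r_full_behavior", "r_full_neural", "joint")],
                       by = "category") |>
      dplyr::rename(joint_reliability = "joint") |>
      dplyr::mutate(roi = res$roi, task = res$task, .before = 1)
  })
  run <- structure(list(
    summary = summary,
    results = results,
    reliability = reliab,
    searchlight = searchlight,
    rois = rois,
    gist = gist_res,
    behavior = scores,
    trials = trials,
    group_vectors = group_vectors,
    exclusions = excl,
    design = design,
    voxel_coords = patterns$voxel_coords,
    warnings = warnings_log,
    config = config
  ), class = "ndba_run")
  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

#' @export
print.ndba_run <- function(x, ...) {
  cat("<ndba_run>\n")
  if (nrow(x$summary) > 0) print(x$summary, n = Inf) else cat("  no completed cells\n")
  if (length(x$warnings) > 0) cat("warnings:\n", paste(" -", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
tidy.ndba_run <- function(x, ...) x$summary

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$summary, file.path(out_dir, "ndba_summary.csv"))
  per_subj <- purrr::map_dfr(run$results, tidy)
  readr::write_csv(per_subj, file.path(out_dir, "ndba_per_subject.csv"))
  readr::write_csv(run$behavior, file.path(out_dir, "behavior_scores.csv"))
  write_behavior_csv(run$trials, file.path(out_dir, "behavior_trials.csv"))
  for (dm in names(run$searchlight)) {
    readr::write_csv(
      searchlight_map(run$searchlight[[dm]]$maps, run$voxel_coords) |>
        dplyr::left_join(run$searchlight[[dm]]$group[c("voxel", "t", "p", "q", "significant")],
                         by = "voxel") |>
        dplyr::mutate(in_roi = .data$voxel %in% run$rois[[dm]]),
      file.path(out_dir, sprintf("searchlight_%s.csv", dm)))
  }
  if (!is.null(run$gist)) {
    readr::write_csv(run$gist, file.path(out_dir, "gist_crossdecoding.csv"))
  }
  report <- list(
    seed = run$config$seed,
    settings = run$config[c("k_neighborhood", "q_threshold", "top_fraction",
                            "k_folds", "n_splits", "rt_basis")],
    n_subjects_kept = length(run$exclusions$kept),
    excluded_subjects = run$exclusions$excluded,
    roi_sizes = lapply(run$rois, length),
    warnings = run$warnings
  )
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
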