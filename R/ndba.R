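#' Percentile-scale a vector
#'
#' Maps values to `100 * (rank - 0.5) / n` using mean ranks for ties: a
#' strictly monotone transform of the ranks, invariant to positive affine
#' transforms of the input. An all-equal input maps to 50 everywhere.
#'
#' @param x Numeric vector of length >= 2.
#' @return Numeric vector in `[0, 100]`.
#' @examples
#' percentile_scale(c(3, 1, 2))  # 83.33, 16.67, 50
#' @export
percentile_scale <- function(x) {
  if (length(x) < 2) ndba_abort("Need >= 2 values.", "ndba_invalid_argument")
  if (anyNA(x)) ndba_abort("`x` must not contain NA.", "ndba_invalid_input")
  100 * (rank(x, ties.method = "average") - 0.5) / length(x)
}

#' Crisscross (city-block) distance combination
#'
#' For a category structure that crisscrosses two represented dimensions (and
#' so is not linearly separable along either), the distances from the two
#' single-dimension boundaries are each scaled to percentiles -- giving both
#' sets equal weight -- and summed, following the rationale of a city-block
#' metric over independently represented dimensions.
#'
#' @param animacy_distances,shape_distances Correct-side signed distances for
#'   the same stimuli (each typically from its own dimension's ROI).
#' @return Combined numeric vector (range 1 to 199 in percentile units).
#' @export
crisscross_distance <- function(animacy_distances, shape_distances) {
  if (length(animacy_distances) != length(shape_distances)) {
    ndba_abort("Distance vectors must have equal length.", "ndba_invalid_argument")
  }
  percentile_scale(animacy_distances) + percentile_scale(shape_distances)
}

#' Correlate per-subject neural distances with the group behavioral vector
#'
#' Pearson correlation, per subject, between the subject's fold-averaged
#' correct-side distances and the group-averaged behavior scores, restricted
#' to a category subset of stimuli. Subjects with zero variance in either
#' vector yield `NA` (logged) and are excluded from group inference.
#'
#' @param distances A tibble `(subject_id, stimulus_id, distance)` -- rows for
#'   several subjects; [crossval_distances()] outputs can be row-bound after
#'   adding `subject_id`.
#' @param group_scores A tibble `(stimulus_id, score)` from
#'   [group_behavior_vector()].
#' @param stimuli Optional stimulus ids restricting to a category subset.
#' @return A tibble `(subject_id, n_stimuli, r)`.
#' @export
correlate_distance_behavior <- function(distances, group_scores, stimuli = NULL) {
  if (!is.null(stimuli)) {
    distances <- dplyr::filter(distances, .data$stimulus_id %in% stimuli)
  }
  x <- dplyr::inner_join(distances, group_scores, by = "stimulus_id")
  if (min(table(x$subject_id)) < 3) {
    ndba_abort("Need >= 3 aligned stimuli per subject.", "ndba_invalid_argument")
  }
  out <- x |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_stimuli = dplyr::n(),
      r = if (sd(.data$distance) > 0 && sd(.data$score) > 0)
            cor(.data$distance, .data$score) else NA_real_,
      .groups = "drop"
    )
  if (anyNA(out$r)) {
    warning("Zero-variance vector(s): correlation undefined for some subjects.")
  }
  out
}

#' Group inference on per-subject correlations
#'
#' One-sample two-sided t-test of the raw correlations against zero (matching
#' how mean correlations are conventionally reported); optionally on
#' Fisher-z-transformed values.
#'
#' @param r Numeric vector of per-subject correlations (NAs dropped).
#' @param fisher_z Test on `atanh(r)` instead of raw `r`.
#' @return A one-row tibble `(mean_r, t, df, p, n)`.
#' @export
group_inference <- function(r, fisher_z = FALSE) {
  r <- r[!is.na(r)]
  if (length(r) < 2) ndba_abort("Need >= 2 subjects.", "ndba_invalid_argument")
  v <- if (fisher_z) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)) else r
  if (sd(v) <= 1e-12 * max(1, abs(mean(v)))) {
    tval <- if (mean(v) == 0) 0 else sign(mean(v)) * Inf
    pval <- if (mean(v) == 0) 1 else 0
  } else {
    tt <- t.test(v)
    tval <- unname(tt$statistic)
    pval <- tt$p.value
  }
  tibble::tibble(mean_r = mean(r), t = tval, df = length(r) - 1L,
                 p = pval, n = length(r))
}

#' Paired test of the category asymmetry
#'
#' Paired two-sided t-test of the within-subject difference between the two
#' categories' distance-behavior correlations.
#'
#' @param r_a,r_b Per-subject correlations, paired by subject.
#' @return A one-row tibble `(mean_diff, t, df, p, n)`.
#' @export
category_asymmetry_test <- function(r_a, r_b) {
  keep <- !is.na(r_a) & !is.na(r_b)
  d <- r_a[keep] - r_b[keep]
  if (length(d) < 2) ndba_abort("Need >= 2 paired subjects.", "ndba_invalid_argument")
  if (sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
    tval <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    pval <- if (mean(d) == 0) 1 else 0
  } else {
    tt <- t.test(d)
    tval <- unname(tt$statistic)
    pval <- tt$p.value
  }
  tibble::tibble(mean_diff = mean(d), t = tval, df = length(d) - 1L,
                 p = pval, n = length(d))
}

#' Distance-to-bound analysis for one ROI and task
#'
#' Correlates each subject's distances with the group behavior vector within
#' each of the task's two categories, runs group inference per category, and
#' tests the category asymmetry.
#'
#' @param distances A tibble `(subject_id, stimulus_id, distance)`.
#' @param group_scores A tibble `(stimulus_id, score)`.
#' @param design The stimulus design tibble.
#' @param task The task whose categories partition the stimuli.
#' @param roi Optional ROI label carried into the output.
#' @param fisher_z Passed to [group_inference()].
#' @return An object of class `ndba_result`: list with `per_subject`
#'   (subject_id, category, r), `summary` (category, mean_r, t, df, p, n),
#'   `asymmetry`, `task`, `roi`.
#' @export
ndba_analysis <- function(distances, group_scores, design, task,
                          roi = NA_character_, fisher_z = FALSE) {
  labels <- task_labels(design, task)
  cats <- levels(labels)
  per_subject <- purrr::map_dfr(cats, function(cat) {
    stim <- design$stimulus_id[labels == cat]
    correlate_distance_behavior(distances, group_scores, stim) |>
      dplyr::mutate(category = cat, .after = "subject_id")
  })
  summary <- per_subject |>
    dplyr::group_by(.data$category) |>
    dplyr::reframe(group_inference(.data$r, fisher_z = fisher_z))
  wide <- tidyr::pivot_wider(per_subject[c("subject_id", "category", "r")],
                             names_from = "category", values_from = "r")
  asym <- category_asymmetry_test(wide[[cats[1]]], wide[[cats[2]]])
  structure(list(per_subject = per_subject, summary = summary,
                 asymmetry = asym, task = task, roi = roi),
            class = "ndba_result")
}

#' @export
print.ndba_result <- function(x, ...) {
  cat(sprintf("<ndba_result> task %s, ROI %s\n", x$task, x$roi))
  print(x$summary)
  cat(sprintf("  asymmetry: mean diff %.3f, t(%d) = %.2f, p = %.3g\n",
              x$asymmetry$mean_diff, x$asymmetry$df, x$asymmetry$t,
              x$asymmetry$p))
  invisible(x)
}

#' @export
tidy.ndba_result <- function(x, ...) {
  dplyr::mutate(x$per_subject, task = x$task, roi = x$roi)
}

#' @export
glance.ndba_result <- function(x, ...) {
  dplyr::mutate(x$summary, task = x$task, roi = x$roi,
                asymmetry_t = x$asymmetry$t, asymmetry_p = x$asymmetry$p)
}
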