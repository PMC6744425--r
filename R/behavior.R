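#' Aggregate trial-level behavior per stimulus
#'
#' Per (subject, task, stimulus): mean and median RT (over correct trials by
#' default, or all trials), proportion error over all trials, and trial count.
#' Cells with no usable RT trials get `NA` RTs and a warning; downstream
#' functions drop them.
#'
#' @param trials Trial tibble with columns `subject_id, task, run, stimulus_id,
#'   rt_ms, correct` (a `rep` column is optional).
#' @param rt_basis `"correct_only"` (default) or `"all"`: which trials enter
#'   the RT summaries.
#' @return A tibble `(subject_id, task, stimulus_id, mean_rt_ms, median_rt_ms,
#'   prop_error, n_trials)`.
#' @export
aggregate_behavior <- function(trials, rt_basis = c("correct_only", "all")) {
  rt_basis <- match.arg(rt_basis)
  if (nrow(trials) == 0) ndba_abort("`trials` is empty.", "ndba_invalid_argument")
  if (any(trials$rt_ms <= 0)) {
    ndba_abort("All `rt_ms` must be positive.", "ndba_invalid_argument")
  }
  agg <- trials |>
    dplyr::group_by(.data$subject_id, .data$task, .data$stimulus_id) |>
    dplyr::summarise(
      mean_rt_ms = mean(.data$rt_ms[if (rt_basis == "correct_only") .data$correct else TRUE]),
      median_rt_ms = median(.data$rt_ms[if (rt_basis == "correct_only") .data$correct else TRUE]),
      prop_error = mean(!.data$correct),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
  if (anyNA(agg$mean_rt_ms)) {
    warning(sprintf("%d cells have no usable RT trials (flagged NA).",
                    sum(is.na(agg$mean_rt_ms))))
  }
  agg
}

#' Subject-level LISAS scaling parameters
#'
#' `S_RT` is the SD of the subject's trial RTs in the task (on the chosen RT
#' basis); `S_PE` is the SD of the subject's trial-level (binary) errors in
#' the task, `sqrt(PE (1 - PE))`. Their ratio converts error proportion into
#' RT units. `pe_basis = "per_stimulus"` instead uses the SD over stimuli of
#' the per-stimulus error proportions (a smaller denominator that weights the
#' error penalty more heavily).
#'
#' @inheritParams aggregate_behavior
#' @param pe_basis `"trial"` (default) or `"per_stimulus"`.
#' @return A tibble `(subject_id, task, s_rt, s_pe)`.
#' @export
lisas_params <- function(trials, rt_basis = c("correct_only", "all"),
                         pe_basis = c("trial", "per_stimulus")) {
  rt_basis <- match.arg(rt_basis)
  pe_basis <- match.arg(pe_basis)
  pe <- if (pe_basis == "trial") {
    trials |>
      dplyr::group_by(.data$subject_id, .data$task) |>
      dplyr::summarise(s_pe = sd(!.data$correct), .groups = "drop")
  } else {
    trials |>
      dplyr::group_by(.data$subject_id, .data$task, .data$stimulus_id) |>
      dplyr::summarise(prop_error = mean(!.data$correct), .groups = "drop_last") |>
      dplyr::summarise(s_pe = sd(.data$prop_error), .groups = "drop")
  }
  rt <- trials |>
    dplyr::filter(if (rt_basis == "correct_only") .data$correct else TRUE) |>
    dplyr::group_by(.data$subject_id, .data$task) |>
    dplyr::summarise(s_rt = sd(.data$rt_ms), .groups = "drop")
  dplyr::left_join(rt, pe, by = c("subject_id", "task"))
}

#' Linearly integrated speed-accuracy score (LISAS)
#'
#' `LISAS = mean_rt + (S_RT / S_PE) * prop_error`: an accuracy-adjusted RT in
#' milliseconds that penalizes errors in units of the subject's own RT spread.
#' When `S_PE = 0` (the subject made no errors anywhere in the task) the score
#' reduces to the mean RT. Always `>= mean_rt`.
#'
#' @param mean_rt Mean RT in ms (nonnegative).
#' @param prop_error Proportion of error trials in `[0, 1]`.
#' @param s_rt,s_pe Subject-level scaling parameters from [lisas_params()].
#' @return LISAS in ms (vectorized).
#' @examples
#' lisas(600, 0.1, s_rt = 100, s_pe = 0.2)  # 650
#' @export
lisas <- function(mean_rt, prop_error, s_rt, s_pe) {
  if (any(mean_rt < 0, na.rm = TRUE) || any(prop_error < 0 | prop_error > 1, na.rm = TRUE) ||
      any(s_rt < 0, na.rm = TRUE) || any(s_pe < 0, na.rm = TRUE)) {
    ndba_abort("LISAS inputs must be nonnegative (prop_error in [0, 1]).",
               "ndba_invalid_argument")
  }
  penalty <- ifelse(s_pe == 0, 0, (s_rt / s_pe) * prop_error)
  mean_rt + penalty
}

#' Per-stimulus behavior scores including LISAS
#'
#' Convenience wrapper: [aggregate_behavior()] plus [lisas_params()] joined
#' and the `lisas_ms` column added.
#'
#' @inheritParams aggregate_behavior
#' @return The aggregated tibble with an extra `lisas_ms` column.
#' @export
behavior_scores <- function(trials, rt_basis = c("correct_only", "all")) {
  rt_basis <- match.arg(rt_basis)
  agg <- aggregate_behavior(trials, rt_basis)
  par <- lisas_params(trials, rt_basis)
  agg |>
    dplyr::left_join(par, by = c("subject_id", "task")) |>
    dplyr::mutate(lisas_ms = lisas(.data$mean_rt_ms, .data$prop_error,
                                   .data$s_rt, .data$s_pe)) |>
    dplyr::select(-"s_rt", -"s_pe")
}

#' Group-averaged behavioral vector
#'
#' Averages the per-subject LISAS scores across (kept) subjects, yielding one
#' behavioral value per stimulus for the task -- the vector the per-subject
#' neural distances are correlated with.
#'
#' @param scores Output of [behavior_scores()].
#' @param task Task to extract.
#' @param keep_subjects Optional subject ids to retain (e.g. after
#'   [exclude_chance_subjects()]).
#' @return A tibble `(stimulus_id, score, n_subjects)`.
#' @export
group_behavior_vector <- function(scores, task, keep_subjects = NULL) {
  x <- dplyr::filter(scores, .data$task == !!task)
  if (!is.null(keep_subjects)) {
    x <- dplyr::filter(x, .data$subject_id %in% keep_subjects)
  }
  if (anyNA(x$lisas_ms)) {
    warning("Dropping cells with missing LISAS from the group vector.")
    x <- dplyr::filter(x, !is.na(.data$lisas_ms))
  }
  x |>
    dplyr::group_by(.data$stimulus_id) |>
    dplyr::summarise(score = mean(.data$lisas_ms),
                     n_subjects = dplyr::n(), .groups = "drop")
}

#' Speed-accuracy coupling diagnostic
#'
#' Per subject and task, the Pearson correlation across stimuli between mean
#' RT and proportion error, plus a group one-sample t-test of the correlations
#' against zero. Under the distance-to-bound model hard stimuli are both slow
#' and error-prone, so the planted coupling makes this correlation positive
#' (equivalently: RT and *accuracy* correlate negatively, the premise of
#' accuracy-adjusted RTs).
#'
#' @param scores Output of [behavior_scores()] (or [aggregate_behavior()]).
#' @return A tibble `(task, n_subjects, mean_r, t, df, p)` with the
#'   per-subject correlations in `attr(, "per_subject")`.
#' @export
rt_accuracy_coupling <- function(scores) {
  per_subject <- scores |>
    dplyr::filter(!is.na(.data$mean_rt_ms)) |>
    dplyr::group_by(.data$subject_id, .data$task) |>
    dplyr::summarise(
      n_stimuli = dplyr::n(),
      r = if (dplyr::n() >= 3 && sd(.data$mean_rt_ms) > 0 && sd(.data$prop_error) > 0)
            cor(.data$mean_rt_ms, .data$prop_error) else NA_real_,
      .groups = "drop"
    )
  safe_inference <- function(r) {
    if (length(r) < 2) {
      return(tibble::tibble(mean_r = mean(r), t = NA_real_, df = 0L,
                            p = NA_real_, n = length(r)))
    }
    group_inference(r)
  }
  out <- per_subject |>
    dplyr::filter(!is.na(.data$r)) |>
    dplyr::group_by(.data$task) |>
    dplyr::reframe(safe_inference(.data$r)) |>
    dplyr::rename(n_subjects = "n")
  attr(out, "per_subject") <- per_subject
  out
}

#' Exclude subjects at chance on any task
#'
#' One-sided exact binomial test of each subject's overall accuracy against
#' 0.5, per task; a subject whose accuracy is not significantly above chance
#' on at least one task is excluded from all analyses.
#'
#' @param trials Trial tibble.
#' @param alpha Test level (default 0.05).
#' @return A list with `kept`, `excluded` (subject id vectors), and `tests`
#'   (tibble: subject_id, task, n, n_correct, accuracy, p, at_chance).
#' @export
exclude_chance_subjects <- function(trials, alpha = 0.05) {
  tests <- trials |>
    dplyr::group_by(.data$subject_id, .data$task) |>
    dplyr::summarise(n = dplyr::n(), n_correct = sum(.data$correct),
                     .groups = "drop") |>
    dplyr::mutate(
      accuracy = .data$n_correct / .data$n,
      p = pbinom(.data$n_correct - 1, .data$n, 0.5, lower.tail = FALSE),
      at_chance = .data$p >= alpha
    )
  excluded <- unique(tests$subject_id[tests$at_chance])
  list(kept = setdiff(unique(tests$subject_id), excluded),
       excluded = excluded,
       tests = tests)
}
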