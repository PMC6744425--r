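#' Generate trial-level behavior from true boundary distances
#'
#' For every subject, task, run, and repeat, one trial per stimulus is drawn.
#' The per-category `asymmetry` multiplier `m` gates the effective distance
#' `m * |d|` that drives performance, so the planted coupling can be confined
#' to one category (as observed empirically for animate stimuli). Reaction
#' time follows the linear distance-to-bound model
#' `RT = intercept + slope * m * |d| + N(0, noise)`, truncated below at
#' 150 ms, where `d` is the stimulus's true boundary distance for the task.
#' Correctness is Bernoulli with
#' `p(correct) = plogis((accuracy_base + m * |d|) / accuracy_link_scale)`:
#' always above 0.5, with an uncoupled category sitting at the flat baseline
#' `plogis(base / scale)`; a scale of `0` is the deterministic limit (all
#' correct). Deterministic given the config seed.
#'
#' @param design A design tibble from [generate_design()].
#' @param true_dists A tibble `(subject_id, task, stimulus_id, distance)`, as
#'   returned by [behavior_true_distances()]; one distance per stimulus per
#'   task per subject.
#' @param config An [synth_config()] object.
#' @return A trial tibble `(subject_id, task, run, rep, stimulus_id, rt_ms,
#'   correct)`.
#' @export
generate_behavior <- function(design, true_dists, config = synth_config()) {
  validate_synth_config(config)
  needed <- tidyr::expand_grid(subject_id = unique(true_dists$subject_id),
                               task = unique(true_dists$task),
                               stimulus_id = design$stimulus_id)
  missing <- dplyr::anti_join(needed, true_dists,
                              by = c("subject_id", "task", "stimulus_id"))
  if (nrow(missing) > 0) {
    ndba_abort("`true_dists` must cover every (subject, task, stimulus).",
               "ndba_invalid_argument")
  }
  n_trials_cell <- config$n_runs_per_task * config$n_repeats_per_run
  rt_floor <- 150

  purrr::map_dfr(split(true_dists, true_dists$subject_id), function(sub_d) {
    sid <- sub_d$subject_id[[1]]
    with_substream(config$seed, "behavior", sid, code = {
      purrr::map_dfr(split(sub_d, sub_d$task), function(task_d) {
        tk <- task_d$task[[1]]
        task_d <- task_d[match(design$stimulus_id, task_d$stimulus_id), ]
        lab <- as.character(task_labels(design, tk))
        mult <- config$asymmetry[[tk]][lab]
        if (any(is.na(mult))) {
          ndba_abort(sprintf("`asymmetry$%s` must name both task categories.", tk),
                     "ndba_invalid_argument")
        }
        d_eff <- unname(mult) * abs(task_d$distance)
        mu <- config$rt_intercept_ms + config$rt_slope_ms_per_distance * d_eff
        p_correct <- if (config$accuracy_link_scale == 0) rep(1, length(d_eff))
                     else plogis((config$accuracy_base + d_eff) /
                                 config$accuracy_link_scale)
        grid <- tidyr::expand_grid(run = seq_len(config$n_runs_per_task),
                                   rep = seq_len(config$n_repeats_per_run),
                                   stimulus_id = design$stimulus_id)
        idx <- match(grid$stimulus_id, design$stimulus_id)
        rt <- pmax(rt_floor,
                   mu[idx] + rnorm(nrow(grid), 0, config$rt_noise_sd_ms))
        correct <- rbinom(nrow(grid), 1, p_correct[idx]) == 1
        tibble::tibble(subject_id = sid, task = tk, run = grid$run,
                       rep = grid$rep, stimulus_id = grid$stimulus_id,
                       rt_ms = rt, correct = correct)
      })
    })
  })
}
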