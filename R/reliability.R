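#' Mean split-half correlation
#'
#' Splits the columns (units: run x repeat pattern estimates, or trials) of a
#' `stimulus x unit` matrix into two balanced halves, correlates the halves'
#' per-stimulus means, and averages over `n_splits` random splits. With
#' exactly two units there is only one split and it is used once.
#'
#' @param x Numeric matrix `[stimulus x unit]` with >= 2 columns.
#' @param n_splits Number of random balanced splits (default 100).
#' @param seed Seed for the split draws.
#' @return Mean split-half Pearson correlation, with attribute `n_splits`.
#' @export
split_half <- function(x, n_splits = 100, seed = 1L) {
  x <- as.matrix(x)
  m <- ncol(x)
  if (m < 2) ndba_abort("Need >= 2 splittable units.", "ndba_cannot_split")
  if (m == 2) {
    r <- cor(x[, 1], x[, 2])
    return(structure(r, n_splits = 1L))
  }
  h <- floor(m / 2)
  rs <- withr::with_seed(seed, {
    vapply(seq_len(n_splits), function(i) {
      half1 <- sample(m, h)
      cor(rowMeans(x[, half1, drop = FALSE]),
          rowMeans(x[, -half1, drop = FALSE]))
    }, numeric(1))
  })
  structure(mean(rs), n_splits = n_splits)
}

#' Spearman-Brown correction
#'
#' Estimates full-length reliability from a half-length reliability:
#' `r_full = 2 r / (1 + r)`. Monotone increasing on `(-1, 1]` with fixed
#' points 0 and 1. Half-reliabilities at (or numerically below) -1 are clamped
#' to -1 and flagged via the `"clamped"` attribute.
#'
#' @param r_half Split-half correlation in `[-1, 1]`.
#' @return Corrected reliability.
#' @examples
#' spearman_brown(0.5)  # 0.6667
#' @export
spearman_brown <- function(r_half) {
  if (any(abs(r_half) > 1, na.rm = TRUE)) {
    ndba_abort("`r_half` must lie in [-1, 1].", "ndba_invalid_argument")
  }
  clamped <- r_half <= -1 + 1e-12
  r <- ifelse(clamped, -1, 2 * r_half / (1 + r_half))
  if (any(clamped, na.rm = TRUE)) attr(r, "clamped") <- TRUE
  r
}

#' Joint reliability (noise ceiling)
#'
#' The square root of the product of the behavior and neural full-set
#' reliabilities: the maximum linear correlation attainable between the two
#' measures given their measurement noise. Undefined (NA, flagged) when the
#' product is negative. Because the distance-behavior correlations are
#' predicted to be negative, plots conventionally display the ceiling with
#' inverted sign (`invert_sign = TRUE`).
#'
#' @param r_full_behavior,r_full_neural Full-set reliabilities in `[-1, 1]`.
#' @param invert_sign Return the negated value for display against negative
#'   correlations.
#' @return The joint reliability, or `NA` with attribute `undefined = TRUE`.
#' @examples
#' joint_reliability(0.64, 0.81)  # 0.72
#' @export
joint_reliability <- function(r_full_behavior, r_full_neural, invert_sign = FALSE) {
  if (any(abs(c(r_full_behavior, r_full_neural)) > 1, na.rm = TRUE)) {
    ndba_abort("Reliabilities must lie in [-1, 1].", "ndba_invalid_argument")
  }
  prod <- r_full_behavior * r_full_neural
  if (is.na(prod) || prod < 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  j <- sqrt(prod)
  if (invert_sign) -j else j
}

#' Split-half reliability of the group behavioral vector
#'
#' Splits each stimulus's run-x-repeat trial units into balanced halves,
#' recomputes the group-averaged LISAS vector within each half (including the
#' half-specific subject scaling parameters), correlates the two half-vectors,
#' and averages over splits.
#'
#' @param trials Trial tibble (must contain a `rep` column).
#' @param task Task to score.
#' @param stimuli Optional stimulus subset (a task category).
#' @param keep_subjects Optional subject ids to retain.
#' @param rt_basis Passed to [behavior_scores()].
#' @param n_splits,seed Split controls.
#' @return Mean split-half correlation (attribute `n_splits`).
#' @export
behavior_split_half <- function(trials, task, stimuli = NULL,
                                keep_subjects = NULL,
                                rt_basis = "correct_only",
                                n_splits = 100, seed = 1L) {
  x <- dplyr::filter(trials, .data$task == !!task)
  if (!is.null(keep_subjects)) x <- dplyr::filter(x, .data$subject_id %in% keep_subjects)
  units <- dplyr::distinct(x, .data$run, .data$rep)
  m <- nrow(units)
  if (m < 2) ndba_abort("Need >= 2 run-x-repeat units.", "ndba_cannot_split")
  h <- floor(m / 2)
  unit_id <- match(paste(x$run, x$rep), paste(units$run, units$rep))

  # Cells with no usable RT trials inside a half are routine at half the trial
  # count; they are silently dropped and the halves joined on stimulus.
  half_vector <- function(rows) {
    gv <- suppressWarnings(
      group_behavior_vector(behavior_scores(x[rows, ], rt_basis), task))
    if (!is.null(stimuli)) gv <- dplyr::filter(gv, .data$stimulus_id %in% stimuli)
    gv
  }
  n_eff <- if (m == 2) 1L else n_splits
  rs <- withr::with_seed(seed, {
    vapply(seq_len(n_eff), function(i) {
      half1 <- if (m == 2) 1L else sample(m, h)
      both <- dplyr::inner_join(half_vector(unit_id %in% half1),
                                half_vector(!unit_id %in% half1),
                                by = "stimulus_id")
      cor(both$score.x, both$score.y)
    }, numeric(1))
  })
  structure(mean(rs), n_splits = n_eff)
}

#' Split-half reliability of neural distances
#'
#' Operates on the held-out per-sample distances from [crossval_distances()]:
#' sample units are split into balanced halves, each half's per-stimulus mean
#' distance is formed, and the half-vectors are correlated. When two distance
#' objects are supplied (animacy and shape classifiers for the crisscross
#' task) the same split is applied to both and each half is combined with
#' [crisscross_distance()] before correlating.
#'
#' @param dists A single `ndba_distances` object, or a list of two (combined
#'   per half via the percentile sum).
#' @param stimuli Optional stimulus-id subset (a task category).
#' @param n_splits,seed Split controls.
#' @return Mean split-half correlation (attribute `n_splits`).
#' @export
neural_split_half <- function(dists, stimuli = NULL, n_splits = 100, seed = 1L) {
  if (inherits(dists, "ndba_distances")) dists <- list(dists)
  mats <- lapply(dists, function(d) attr(d, "sample_distances"))
  ids <- dists[[1]]$stimulus_id
  keep <- if (is.null(stimuli)) seq_along(ids) else which(ids %in% stimuli)
  m <- ncol(mats[[1]])
  if (m < 2) ndba_abort("Need >= 2 sample units.", "ndba_cannot_split")
  h <- floor(m / 2)
  combine <- function(halves) {
    if (length(halves) == 1) halves[[1]][keep]
    else crisscross_distance(halves[[1]], halves[[2]])[keep]
  }
  n_eff <- if (m == 2) 1L else n_splits
  rs <- withr::with_seed(seed, {
    vapply(seq_len(n_eff), function(i) {
      half1 <- if (m == 2) 1L else sample(m, h)
      v1 <- combine(lapply(mats, function(x) rowMeans(x[, half1, drop = FALSE])))
      v2 <- combine(lapply(mats, function(x) rowMeans(x[, -half1, drop = FALSE])))
      cor(v1, v2)
    }, numeric(1))
  })
  structure(mean(rs), n_splits = n_eff)
}

#' Joint reliability estimate for one analysis cell
#'
#' Bundles the behavior and neural split-half reliabilities, their
#' Spearman-Brown corrections, and the joint ceiling.
#'
#' @param r_half_behavior,r_half_neural Mean split-half correlations.
#' @return A one-row tibble `(r_half_behavior, r_half_neural, r_full_behavior,
#'   r_full_neural, joint)`.
#' @export
reliability_estimate <- function(r_half_behavior, r_half_neural) {
  rb <- spearman_brown(as.numeric(r_half_behavior))
  rn <- spearman_brown(as.numeric(r_half_neural))
  tibble::tibble(
    r_half_behavior = as.numeric(r_half_behavior),
    r_half_neural = as.numeric(r_half_neural),
    r_full_behavior = as.numeric(rb),
    r_full_neural = as.numeric(rn),
    joint = as.numeric(joint_reliability(as.numeric(rb), as.numeric(rn)))
  )
}
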