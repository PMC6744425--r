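# Shared fixtures and independent oracles for the test suite.

# Small synthetic config: 300-voxel grid, the two 150-voxel planted slabs fill
# it completely (no background), so pattern generation and distance
# cross-validation are fast. Study-condition effect parameters are the
# package defaults.
small_config <- function(seed = 1L, ...) {
  dims <- c(10L, 5L, 6L)
  synth_config(
    grid_dims = dims,
    region_layout = list(
      loc_like = block_indices(dims, 1:10, 1:5, 1:3),
      evc_like = block_indices(dims, 1:10, 1:5, 4:6)
    ),
    seed = seed,
    ...
  )
}

# Null config: no planted RT-distance coupling and error-free responses, so
# LISAS reduces to pure RT noise (the calibration condition).
null_config <- function(seed = 1L, ...) {
  small_config(seed = seed, rt_slope_ms_per_distance = 0,
               accuracy_link_scale = 0, ...)
}

# One simulated distance-to-bound replicate on the small config: planted-block
# distances for the requested task, LISAS group vector, per-category group
# inference, and the paired asymmetry test. Returns the ndba_result plus
# hooks used by several tests.
simulate_ndba_replicate <- function(seed, config = small_config(seed = seed),
                                    task = "animacy", k = 5) {
  design <- generate_design(8, bar_clusters = config$bar_clusters)
  patterns <- generate_patterns(design, config)
  trials <- generate_behavior(design, behavior_true_distances(patterns), config)
  excl <- exclude_chance_subjects(trials)
  scores <- suppressWarnings(behavior_scores(trials))
  gv <- suppressWarnings(
    group_behavior_vector(scores, task, keep_subjects = excl$kept))
  kept <- Filter(function(p) p$subject_id %in% excl$kept, patterns$subjects)

  roi_of <- c(animacy = "loc_like", shape = "evc_like")
  dims_needed <- if (task == "indoor_outdoor") c("animacy", "shape") else task
  dist_objs <- lapply(setNames(nm = dims_needed), function(dm) {
    lapply(kept, function(p) {
      crossval_distances(p, task_labels(design, dm),
                         voxels = config$region_layout[[roi_of[[dm]]]],
                         k = k, seed = substream_seed(seed, "folds", dm, p$subject_id))
    })
  })
  dist_tbl <- purrr::map_dfr(seq_along(kept), function(j) {
    if (task == "indoor_outdoor") {
      da <- dist_objs$animacy[[j]]; ds <- dist_objs$shape[[j]]
      tibble::tibble(subject_id = kept[[j]]$subject_id,
                     stimulus_id = da$stimulus_id,
                     distance = crisscross_distance(da$distance, ds$distance))
    } else {
      d <- dist_objs[[task]][[j]]
      tibble::tibble(subject_id = kept[[j]]$subject_id,
                     stimulus_id = d$stimulus_id, distance = d$distance)
    }
  })
  res <- ndba_analysis(dist_tbl, gv, design, task)
  list(result = res, design = design, patterns = patterns, trials = trials,
       scores = scores, group_vector = gv, dist_objs = dist_objs,
       dist_tbl = dist_tbl, excl = excl, config = config)
}

# Definitional Benjamini-Hochberg step-up: q_i = min over j >= i of p_(j)*m/j,
# mapped back to the input order (independent of stats::p.adjust).
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Closed-form pooled-covariance LDA direction (independent matrix-inverse
# oracle used against fit_lda at shrinkage = 0).
oracle_lda_direction <- function(x, y) {
  y <- factor(y)
  x0 <- x[y == levels(y)[1], , drop = FALSE]
  x1 <- x[y == levels(y)[2], , drop = FALSE]
  s <- (crossprod(sweep(x0, 2, colMeans(x0))) +
        crossprod(sweep(x1, 2, colMeans(x1)))) / (nrow(x) - 2)
  solve(s) %*% (colMeans(x1) - colMeans(x0))
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Two well-separated Gaussian clouds for basic classifier checks.
two_clouds <- function(n = 20, p = 4, sep = 6, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n * p), n), matrix(rnorm(n * p, sep), n))
    list(x = x, y = factor(rep(c("a", "b"), each = n)))
  })
}
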