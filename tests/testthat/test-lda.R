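test_that("unshrunk discriminant matches the closed-form oracle", {
  # small well-conditioned instances: w must equal Sigma^-1 (mu1 - mu0)
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- sample(6:10, 1); p <- sample(2:4, 1)
      x <- matrix(rnorm(n * p), n)
      y <- factor(rep(c("a", "b"), length.out = n))
    })
    fit <- fit_lda(x, y, shrinkage = 0)
    expect_gt(cosine_sim(fit$w, oracle_lda_direction(x, y)), 1 - 1e-10)
    # the class-mean midpoint sits on the boundary
    mid <- (fit$class_means[1, ] + fit$class_means[2, ]) / 2
    expect_lt(abs(signed_distance(fit, mid)), 1e-10)
  }
})

test_that("separable and null data give the expected accuracies", {
  tc <- two_clouds(sep = 8, seed = 2)
  fit <- fit_lda(tc$x, tc$y)
  expect_equal(mean(predict(fit, tc$x) == tc$y), 1)
  # identical class means: held-out accuracy near chance
  withr::with_seed(3, {
    xtr <- matrix(rnorm(400), 100)
    xte <- matrix(rnorm(400), 100)
    y <- factor(rep(c("a", "b"), 50))
  })
  fit0 <- fit_lda(xtr, y)
  expect_lt(abs(mean(predict(fit0, xte) == y) - 0.5), 3 * sqrt(0.25 / 100))
})

test_that("signed distance is a true geometric distance", {
  tc <- two_clouds(seed = 4)
  fit <- fit_lda(tc$x, tc$y, shrinkage = 0.3)
  withr::with_seed(5, pts <- matrix(rnorm(5 * ncol(tc$x)), 5))
  # oracle: orthogonal projection distance onto {x: w.x + b = 0}
  oracle <- (pts %*% fit$w + fit$b) / sqrt(sum(fit$w^2))
  expect_equal(signed_distance(fit, pts), drop(oracle))
  # invariant to positive rescaling of (w, b)
  scaled <- fit
  scaled$w <- fit$w * 7.3; scaled$b <- fit$b * 7.3
  expect_equal(signed_distance(scaled, pts), signed_distance(fit, pts))
  # correct-side convention flips the sign for the first class
  d_lab <- signed_distance(fit, tc$x, tc$y)
  d_raw <- signed_distance(fit, tc$x)
  expect_equal(d_lab[tc$y == "a"], -d_raw[tc$y == "a"])
  expect_equal(d_lab[tc$y == "b"], d_raw[tc$y == "b"])
})

test_that("fit errors are classed and shrinkage keeps p >> n solvable", {
  tc <- two_clouds(seed = 6)
  expect_error(fit_lda(tc$x[tc$y == "a", ], tc$y[tc$y == "a"]),
               class = "ndba_invalid_argument")
  expect_error(fit_lda(tc$x, tc$y, shrinkage = 1.5),
               class = "ndba_invalid_argument")
  # searchlight regime: 100 features, 12 samples; every shrinkage > 0 fits
  withr::with_seed(7, x <- matrix(rnorm(12 * 100), 12))
  y <- factor(rep(c("a", "b"), 6))
  for (s in list("lw", 0.1, 1)) {
    fit <- fit_lda(x, y, shrinkage = s)
    expect_true(all(is.finite(fit$w)))
    expect_gt(sqrt(sum(fit$w^2)), 0)
  }
})

test_that("prediction agrees with the sign of the correct-side distance", {
  tc <- two_clouds(sep = 2, seed = 8)
  fit <- fit_lda(tc$x, tc$y)
  pred <- predict(fit, tc$x)
  d <- signed_distance(fit, tc$x, tc$y)
  expect_equal(pred == tc$y, d > 0)
})

test_that("cross-validated distances recover planted exemplar structure", {
  design <- generate_design(8)
  # near-noise-free: fold-averaged distances rank-match the planted distances
  cfg <- small_config(seed = 9, run_noise_sd = 0.05)
  pat <- generate_patterns(design, cfg)
  # strong fixed shrinkage: in the near-noise-free regime the within-class
  # scatter is concentrated along the planted direction, so the analytic
  # shrinkage under-regularizes the p ~ n pooled covariance
  d <- crossval_distances(pat$subjects[[1]], task_labels(design, "animacy"),
                          voxels = cfg$region_layout$loc_like, seed = 1,
                          shrinkage = 0.9)
  truth <- dplyr::filter(pat$subjects[[1]]$true_distances, dimension == "animacy")
  expect_gt(cor(d$distance, truth$distance, method = "spearman"), 0.99)
  expect_equal(d$n_samples, rep(6, 32))
  expect_equal(dim(attr(d, "sample_distances")), c(32, 6))
  expect_equal(d$distance, rowMeans(attr(d, "sample_distances")))
})

test_that("permuted labels destroy the distance-truth correlation", {
  design <- generate_design(8)
  cfg <- small_config(seed = 10)
  pat <- generate_patterns(design, cfg)
  truth <- dplyr::filter(pat$subjects[[1]]$true_distances, dimension == "animacy")
  labs <- task_labels(design, "animacy")
  r_true <- cor(crossval_distances(pat$subjects[[1]], labs,
                                   voxels = cfg$region_layout$loc_like,
                                   seed = 1)$distance, truth$distance)
  r_perm <- withr::with_seed(11, vapply(1:20, function(i) {
    cor(crossval_distances(pat$subjects[[1]], sample(labs),
                           voxels = cfg$region_layout$loc_like,
                           seed = i)$distance, truth$distance)
  }, numeric(1)))
  expect_gt(r_true, 0.8)
  expect_lt(abs(mean(r_perm)), 2 * sd(r_perm) / sqrt(length(r_perm)) + 0.15)
  expect_gt(r_true, max(abs(r_perm)))
})

test_that("leave-one-run-out accuracy matches a brute-force recount", {
  design <- generate_design(2)  # 8 stimuli, tiny instance
  dims <- c(4L, 3L, 2L)
  cfg <- synth_config(n_subjects = 1, grid_dims = dims,
                      region_layout = list(loc_like = 1:12, evc_like = 13:24),
                      seed = 12)
  pat <- generate_patterns(design, cfg)
  sub <- pat$subjects[[1]]
  labs <- task_labels(design, "animacy")
  res <- crossval_accuracy(sub, labs, shrinkage = 0.5)
  # independent recount: manual loop over runs with the same fits
  fl <- ndbar:::flatten_patterns(sub)
  y <- factor(labs)[fl$info$stimulus]
  correct <- 0
  for (r in 1:3) {
    tr <- fl$info$run != r
    fit <- fit_lda(fl$x[tr, ], y[tr], shrinkage = 0.5)
    correct <- correct + sum(predict(fit, fl$x[!tr, ]) == y[!tr])
  }
  expect_equal(res$accuracy, correct / nrow(fl$x))
  expect_equal(nrow(res$per_fold), 3)
})

test_that("cross-decoding generalizes planted signal but not cluster-specific signal", {
  design <- generate_design(8)
  cfg <- small_config(seed = 13)
  pat <- generate_patterns(design, cfg)
  sub <- pat$subjects[[1]]
  gen <- cross_decode(sub, design, "animacy", voxels = cfg$region_layout$loc_like)
  expect_gt(attr(gen, "mean_accuracy"), 0.7)
  # constructed counterexample: flip the animacy signal in two clusters so it
  # does not generalize across the cross-decoding folds
  flipped <- sub
  flip_stim <- design$cluster %in% c("pets", "vegetables")
  vox <- cfg$region_layout$loc_like
  sgn <- ifelse(design$animacy == "animate", 1, -1) * cfg$signal_sd$loc_like[["animacy"]]
  for (i in which(flip_stim)) {
    flipped$values[i, , vox] <- flipped$values[i, , vox] - 2 * sgn[i] *
      (1 + 0)  # remove and invert the class-mean shift (offsets left in place)
  }
  anti <- cross_decode(flipped, design, "animacy", voxels = vox)
  expect_lt(attr(anti, "mean_accuracy"), 0.25)  # systematically anti-generalizes
  # train/test never share stimuli: accuracy rows carry disjoint cluster pairs
  expect_false(any(strsplit(gen$train_clusters[1], "\\+")[[1]] %in%
                   strsplit(gen$train_clusters[2], "\\+")[[1]]))
})
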