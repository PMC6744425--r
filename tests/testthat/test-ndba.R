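test_that("percentile scaling follows the mean-rank formula", {
  expect_equal(percentile_scale(c(3, 1, 2)), c(83.33333, 16.66667, 50),
               tolerance = 1e-6)
  # ties take the mean rank: ranks (1.5, 1.5, 3) / n = 3
  expect_equal(percentile_scale(c(1, 1, 2)),
               100 * (c(1.5, 1.5, 3) - 0.5) / 3)
  # brute-force mean-rank oracle on random tied vectors
  withr::with_seed(51, {
    for (i in 1:20) {
      x <- sample(1:5, 12, replace = TRUE)
      ranks <- vapply(seq_along(x), function(j) {
        mean(which(sort(x) == x[j]))  # mean position among sorted values
      }, numeric(1))
      expect_equal(percentile_scale(x), 100 * (ranks - 0.5) / length(x))
    }
  })
  # affine invariance and order isomorphism
  withr::with_seed(52, x <- rnorm(30))
  expect_equal(percentile_scale(3.2 * x + 11), percentile_scale(x))
  expect_identical(order(percentile_scale(x)), order(x))
  expect_equal(percentile_scale(rep(7, 5)), rep(50, 5))
  expect_error(percentile_scale(1), class = "ndba_invalid_argument")
})

test_that("crisscross combination is symmetric with equal dimension weights", {
  withr::with_seed(53, {a <- rnorm(32); b <- rnorm(32)})
  expect_equal(crisscross_distance(a, b), crisscross_distance(b, a))
  expect_equal(crisscross_distance(a, a), 2 * percentile_scale(a))
  # reversed ranks cancel to a constant 100
  x <- 1:10
  expect_equal(crisscross_distance(x, rev(x)), rep(100, 10))
  expect_error(crisscross_distance(a, b[-1]), class = "ndba_invalid_argument")
})

test_that("distance-behavior correlation matches the closed form", {
  # 4-point hand fixture against the covariance/SD formula
  d <- c(1, 2, 3, 5); s <- c(10, 7, 6, 1)
  r_oracle <- sum((d - mean(d)) * (s - mean(s))) /
    sqrt(sum((d - mean(d))^2) * sum((s - mean(s))^2))
  res <- correlate_distance_behavior(
    tibble::tibble(subject_id = "s1", stimulus_id = 0:3, distance = d),
    tibble::tibble(stimulus_id = 0:3, score = s))
  expect_equal(res$r, r_oracle)
  # exact anticorrelation
  res2 <- correlate_distance_behavior(
    tibble::tibble(subject_id = "s1", stimulus_id = 0:9, distance = 1:10),
    tibble::tibble(stimulus_id = 0:9, score = -(1:10)))
  expect_equal(res2$r, -1)
  # zero variance flagged as NA with a warning
  expect_warning(
    res3 <- correlate_distance_behavior(
      tibble::tibble(subject_id = "s1", stimulus_id = 0:3, distance = rep(1, 4)),
      tibble::tibble(stimulus_id = 0:3, score = 1:4)),
    "Zero-variance")
  expect_true(is.na(res3$r))
  expect_error(correlate_distance_behavior(
    tibble::tibble(subject_id = "s1", stimulus_id = 0:1, distance = 1:2),
    tibble::tibble(stimulus_id = 0:1, score = 1:2)),
    class = "ndba_invalid_argument")
})

test_that("group inference matches a closed-form t and guards degeneracy", {
  r <- c(-0.5, -0.3, -0.6, -0.4, -0.45)
  gi <- group_inference(r)
  t_oracle <- mean(r) / (sd(r) / sqrt(5))
  expect_equal(gi$t, t_oracle)
  expect_equal(gi$p, 2 * pt(-abs(t_oracle), df = 4))
  expect_equal(gi$df, 4L)
  # symmetric about zero
  expect_equal(group_inference(c(-0.2, 0.2, -0.1, 0.1))$t, 0)
  # all equal and nonzero: overflow guarded
  gi_inf <- group_inference(rep(-0.4, 6))
  expect_equal(gi_inf$t, -Inf)
  expect_equal(gi_inf$p, 0)
  expect_equal(group_inference(rep(0, 4))$p, 1)
  # fisher-z option preserves the mean-r report but transforms the test
  gz <- group_inference(r, fisher_z = TRUE)
  expect_equal(gz$mean_r, mean(r))
  expect_equal(gz$t, mean(atanh(r)) / (sd(atanh(r)) / sqrt(5)))
})

test_that("category asymmetry test is a paired t-test", {
  ra <- c(-0.6, -0.5, -0.7, -0.55)
  rb <- c(-0.1, 0.05, -0.2, -0.02)
  at <- category_asymmetry_test(ra, rb)
  d <- ra - rb
  expect_equal(at$t, mean(d) / (sd(d) / sqrt(4)))
  expect_equal(at$p, t.test(ra, rb, paired = TRUE)$p.value)
  # identical vectors: t = 0, p = 1
  same <- category_asymmetry_test(ra, ra)
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  # constant nonzero difference: p -> 0
  shift <- category_asymmetry_test(ra, ra + 0.3)
  expect_equal(shift$p, 0)
})

test_that("ndba_analysis assembles per-category results and tidiers", {
  design <- generate_design(8)
  withr::with_seed(54, {
    dist_tbl <- tidyr::expand_grid(subject_id = sprintf("s%d", 1:5),
                                   stimulus_id = design$stimulus_id) |>
      dplyr::mutate(distance = rnorm(dplyr::n()))
    gv <- tibble::tibble(stimulus_id = design$stimulus_id,
                         score = rnorm(32, 800, 50))
  })
  res <- ndba_analysis(dist_tbl, gv, design, "animacy", roi = "roi_animacy")
  expect_setequal(unique(res$per_subject$category), c("animate", "inanimate"))
  expect_equal(nrow(res$per_subject), 10)
  expect_equal(res$summary$df, c(4L, 4L))
  expect_true(all(abs(res$summary$mean_r) <= 1))
  td <- tidy(res); gl <- glance(res)
  expect_equal(nrow(td), 10)
  expect_equal(gl$task, c("animacy", "animacy"))
  expect_true("asymmetry_p" %in% names(gl))
})
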