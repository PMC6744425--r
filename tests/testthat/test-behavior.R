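make_trials <- function(rt, correct, stimulus = 1L, subject = "s1",
                        task = "animacy") {
  tibble::tibble(subject_id = subject, task = task,
                 run = rep_len(1:3, length(rt)), rep = 1L,
                 stimulus_id = stimulus, rt_ms = rt, correct = correct)
}

test_that("aggregation reproduces hand counts and a brute-force recount", {
  t1 <- make_trials(seq(700, 750, 10), rep(TRUE, 6))
  a1 <- aggregate_behavior(t1)
  expect_equal(a1$prop_error, 0)
  expect_equal(a1$mean_rt_ms, mean(seq(700, 750, 10)))
  t2 <- make_trials(c(800, 900), c(TRUE, FALSE))
  a2 <- aggregate_behavior(t2, rt_basis = "all")
  expect_equal(a2$prop_error, 0.5)
  expect_equal(a2$mean_rt_ms, 850)
  # correct-only basis uses only the correct trial
  expect_equal(aggregate_behavior(t2)$mean_rt_ms, 800)

  # 50-trial random fixture vs. independent base-R recount
  withr::with_seed(41, {
    tr <- tibble::tibble(
      subject_id = sample(c("s1", "s2"), 50, TRUE),
      task = "shape", run = sample(1:3, 50, TRUE), rep = sample(1:2, 50, TRUE),
      stimulus_id = sample(0:4, 50, TRUE),
      rt_ms = runif(50, 300, 1200), correct = runif(50) > 0.2)
  })
  agg <- aggregate_behavior(tr, rt_basis = "all")
  for (i in seq_len(nrow(agg))) {
    rows <- tr$subject_id == agg$subject_id[i] & tr$stimulus_id == agg$stimulus_id[i]
    expect_equal(agg$mean_rt_ms[i], mean(tr$rt_ms[rows]))
    expect_equal(agg$median_rt_ms[i], median(tr$rt_ms[rows]))
    expect_equal(agg$prop_error[i], mean(!tr$correct[rows]))
    expect_equal(agg$n_trials[i], sum(rows))
  }
  expect_error(aggregate_behavior(tr[0, ]), class = "ndba_invalid_argument")
})

test_that("LISAS arithmetic, identities, and invariants", {
  expect_equal(lisas(600, 0.1, s_rt = 100, s_pe = 0.2), 650)
  expect_equal(lisas(600, 0, s_rt = 100, s_pe = 0.2), 600)   # no errors
  expect_equal(lisas(600, 0.1, s_rt = 100, s_pe = 0), 600)   # S_PE = 0 guard
  # doubling S_RT doubles only the penalty term
  base <- lisas(600, 0.1, 100, 0.2)
  expect_equal(lisas(600, 0.1, 200, 0.2) - 600, 2 * (base - 600))
  expect_error(lisas(-1, 0.1, 100, 0.2), class = "ndba_invalid_argument")
  expect_error(lisas(600, 1.2, 100, 0.2), class = "ndba_invalid_argument")
  # LISAS >= mean RT always on realistic scores
  withr::with_seed(42, {
    mrt <- runif(50, 400, 1000); pe <- runif(50, 0, 0.5)
    expect_true(all(lisas(mrt, pe, 120, 0.15) >= mrt))
  })
})

test_that("behavior scores join subject-level scaling correctly", {
  withr::with_seed(43, {
    tr <- tidyr::expand_grid(subject_id = c("s1", "s2"), task = "animacy",
                             run = 1:3, rep = 1:2, stimulus_id = 0:7) |>
      dplyr::mutate(rt_ms = runif(dplyr::n(), 400, 900),
                    correct = runif(dplyr::n()) > 0.15)
  })
  sc <- behavior_scores(tr)
  par <- lisas_params(tr)
  one <- dplyr::filter(sc, subject_id == "s1", stimulus_id == 3)
  p1 <- dplyr::filter(par, subject_id == "s1")
  expect_equal(one$lisas_ms,
               one$mean_rt_ms + p1$s_rt / p1$s_pe * one$prop_error)
})

test_that("group vector averages kept subjects per stimulus", {
  sc <- tibble::tibble(
    subject_id = rep(c("s1", "s2", "s3"), each = 3), task = "shape",
    stimulus_id = rep(0:2, 3), mean_rt_ms = 500, median_rt_ms = 500,
    prop_error = 0, n_trials = 6,
    lisas_ms = c(1, 2, 3, 4, 5, 6, 7, 8, 9))
  gv <- group_behavior_vector(sc, "shape")
  expect_equal(gv$score, c(4, 5, 6))  # mean over the three subjects
  gv2 <- group_behavior_vector(sc, "shape", keep_subjects = c("s1", "s2"))
  expect_equal(gv2$score, c(2.5, 3.5, 4.5))
  gv1 <- group_behavior_vector(sc, "shape", keep_subjects = "s1")
  expect_equal(gv1$score, c(1, 2, 3))  # single subject passthrough
})

test_that("speed-accuracy coupling has the planted positive RT-error sign", {
  # perfectly linear fixture: r = sign(b) exactly
  sc <- tibble::tibble(subject_id = "s1", task = "animacy", stimulus_id = 0:5,
                       mean_rt_ms = 500 + 40 * (0:5), median_rt_ms = 500,
                       prop_error = 0.05 * (0:5), n_trials = 6, lisas_ms = 500)
  cp <- rt_accuracy_coupling(sc)
  expect_equal(attr(cp, "per_subject")$r, 1)
  sc$prop_error <- rev(sc$prop_error)
  expect_equal(attr(rt_accuracy_coupling(sc), "per_subject")$r, -1)

  # planted coupling: hard (near-boundary) stimuli are slow AND error-prone,
  # so RT and proportion error correlate positively across stimuli
  design <- generate_design(8)
  cfg <- small_config(seed = 44)
  pat <- generate_patterns(design, cfg)
  trials <- generate_behavior(design, behavior_true_distances(pat), cfg)
  cp2 <- rt_accuracy_coupling(suppressWarnings(behavior_scores(trials)))
  anim <- dplyr::filter(cp2, task == "animacy")
  expect_gt(anim$mean_r, 0)
  expect_lt(anim$p, 0.05)

  # independent RT and error: mean r near zero
  withr::with_seed(45, {
    sc0 <- tidyr::expand_grid(subject_id = sprintf("s%d", 1:12), task = "x",
                              stimulus_id = 0:15) |>
      dplyr::mutate(mean_rt_ms = runif(dplyr::n(), 500, 700),
                    median_rt_ms = 600,
                    prop_error = runif(dplyr::n(), 0, 0.3),
                    n_trials = 6, lisas_ms = mean_rt_ms)
  })
  cp0 <- rt_accuracy_coupling(sc0)
  expect_lt(abs(cp0$mean_r), 0.25)
  expect_gt(cp0$p, 0.05)
})

test_that("at-chance subjects are excluded by the exact binomial rule", {
  tr_chance <- tibble::tibble(subject_id = "s1", task = "animacy",
                              run = 1, rep = 1, stimulus_id = 1,
                              rt_ms = 500,
                              correct = rep(c(TRUE, FALSE), 96))
  tr_good <- dplyr::mutate(tr_chance, subject_id = "s2",
                           correct = rep(c(TRUE, TRUE, TRUE, TRUE, FALSE),
                                         length.out = 192) |> head(192))
  ex <- exclude_chance_subjects(dplyr::bind_rows(tr_chance, tr_good))
  expect_identical(ex$excluded, "s1")   # accuracy 0.5 on 192 trials
  expect_identical(ex$kept, "s2")       # accuracy 0.8
  # boundary case agrees with the exact binomial tail sum
  k_crit <- min(which(pbinom(0:192 - 1, 192, 0.5, lower.tail = FALSE) < 0.05)) - 1
  for (k in c(k_crit - 1, k_crit)) {
    tr <- tibble::tibble(subject_id = "sb", task = "animacy", run = 1, rep = 1,
                         stimulus_id = 1, rt_ms = 500,
                         correct = rep(c(TRUE, FALSE), c(k, 192 - k)))
    ex <- exclude_chance_subjects(tr)
    manual_p <- sum(dbinom(k:192, 192, 0.5))
    expect_equal(ex$tests$p, manual_p)
    expect_identical(ex$tests$at_chance, manual_p >= 0.05)
  }
})
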