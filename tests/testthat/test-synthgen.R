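design <- generate_design(8)

test_that("pattern generation is deterministic and well-shaped", {
  cfg <- small_config(seed = 11)
  p1 <- generate_patterns(design, cfg)
  p2 <- generate_patterns(design, cfg)
  expect_identical(p1$subjects[[1]]$values, p2$subjects[[1]]$values)
  expect_identical(true_distances(p1), true_distances(p2))
  expect_equal(dim(p1$subjects[[1]]$values), c(32, 6, cfg$n_voxels))
  expect_true(all(is.finite(p1$subjects[[1]]$values)))
  expect_false(anyDuplicated(p1$voxel_coords) > 0)
  # different seeds decouple
  p3 <- generate_patterns(design, small_config(seed = 12))
  expect_false(identical(p1$subjects[[1]]$values, p3$subjects[[1]]$values))
})

test_that("null signal gives chance-level decoding", {
  cfg <- small_config(seed = 3,
                      signal_sd = list(loc_like = c(animacy = 0),
                                       evc_like = c(shape = 0)))
  pat <- generate_patterns(design, cfg)
  acc <- crossval_accuracy(pat$subjects[[1]], task_labels(design, "animacy"),
                           voxels = cfg$region_layout$loc_like)
  # binomial error band around 0.5 at n = 192 held-out samples
  expect_lt(abs(acc$accuracy - 0.5), 3 * sqrt(0.25 / 192))
})

test_that("planted animacy signal is decodable from its block, not background", {
  cfg <- small_config(seed = 4)
  pat <- generate_patterns(design, cfg)
  sub <- pat$subjects[[1]]
  in_block <- crossval_accuracy(sub, task_labels(design, "animacy"),
                                voxels = cfg$region_layout$loc_like)
  expect_gt(in_block$accuracy, 0.75)
  # the shape block carries no animacy class signal
  off_block <- crossval_accuracy(sub, task_labels(design, "animacy"),
                                 voxels = cfg$region_layout$evc_like)
  expect_lt(off_block$accuracy, in_block$accuracy - 0.2)
})

test_that("generator rejects invalid configurations", {
  expect_error(small_config(run_noise_sd = 0), class = "ndba_invalid_argument")
  expect_error(small_config(exemplar_offset_sd = -1), class = "ndba_invalid_argument")
  dims <- c(10L, 5L, 6L)
  expect_error(
    synth_config(grid_dims = dims,
                 region_layout = list(a = 1:10, b = 5:20),
                 signal_sd = list(a = c(animacy = 1))),
    class = "ndba_invalid_argument")  # overlapping regions
  expect_error(
    synth_config(grid_dims = dims, region_layout = list(),
                 signal_sd = list(loc_like = c(animacy = 0.2))),
    class = "ndba_invalid_argument")  # signal without regions
})

test_that("behavior generator couples RT to |true distance| as configured", {
  # noise-free limit: perfect rank anticorrelation within the coupled category
  cfg <- small_config(seed = 6, rt_noise_sd_ms = 1e-9, accuracy_link_scale = 0)
  pat <- generate_patterns(design, cfg)
  td <- behavior_true_distances(pat)
  trials <- generate_behavior(design, td, cfg)
  one <- dplyr::filter(trials, subject_id == "sub-01", task == "animacy")
  agg <- one |> dplyr::group_by(stimulus_id) |>
    dplyr::summarise(rt = mean(rt_ms), .groups = "drop")
  tdi <- dplyr::filter(td, subject_id == "sub-01", task == "animacy")
  animate <- design$stimulus_id[design$animacy == "animate"]
  r_animate <- cor(agg$rt[agg$stimulus_id %in% animate],
                   abs(tdi$distance[tdi$stimulus_id %in% animate]),
                   method = "spearman")
  expect_equal(r_animate, -1)
  # uncoupled category (asymmetry multiplier 0): flat RTs
  inan <- design$stimulus_id[design$animacy == "inanimate"]
  expect_lt(sd(agg$rt[agg$stimulus_id %in% inan]), 1e-6)
})

test_that("behavior trials follow design counts, floor, and accuracy link", {
  cfg <- small_config(seed = 7)
  pat <- generate_patterns(design, cfg)
  trials <- generate_behavior(design, behavior_true_distances(pat), cfg)
  expect_equal(nrow(trials), cfg$n_subjects * 3 * 32 * 6)
  expect_true(all(trials$rt_ms >= 150))
  expect_gt(mean(trials$correct), 0.75)  # logistic link at the default scale
  # deterministic accuracy limit
  cfg0 <- small_config(seed = 7, accuracy_link_scale = 0)
  t0 <- generate_behavior(design, behavior_true_distances(pat), cfg0)
  expect_true(all(t0$correct))
  # missing distances rejected
  td <- behavior_true_distances(pat)
  expect_error(generate_behavior(design, td[-1, ], cfg),
               class = "ndba_invalid_argument")
})

test_that("images encode shape but not animacy, deterministically", {
  imgs <- generate_images(design, size = 96, seed = 9)
  aspects <- vapply(imgs, image_aspect_ratio, numeric(1))
  expect_true(all(aspects[design$shape == "bar"] > 2))
  expect_true(all(aspects[design$shape == "blob"] < 1.5))
  imgs2 <- generate_images(design, size = 96, seed = 9)
  expect_identical(imgs, imgs2)
  expect_error(generate_images(design, size = 32), class = "ndba_invalid_argument")
})
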