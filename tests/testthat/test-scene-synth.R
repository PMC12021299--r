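# Synthetic scene generator: crowd-size calibration, geometry, grouping,
# clustering, determinism.

test_that("crowd sizes match the calibrated distribution and are reproducible", {
  cfg <- generator_config()
  draws <- withr::with_seed(101, sample_crowd_sizes(cfg, 10000))
  expect_true(all(draws >= 2 & draws <= 67))
  expect_lte(abs(stats::median(draws) - 7), 1)
  expect_gte(stats::sd(draws), 6.5)
  expect_lte(stats::sd(draws), 9.0)

  point <- generator_config(crowd_dist = list(family = "point", value = 5))
  expect_true(all(withr::with_seed(1, sample_crowd_sizes(point, 500)) == 5))

  expect_identical(withr::with_seed(7, sample_crowd_sizes(cfg, 100)),
                   withr::with_seed(7, sample_crowd_sizes(cfg, 100)))

  # truncation window with no mass is a configuration error
  bad <- generator_config(crowd_dist = list(family = "point", value = 99))
  expect_error(sample_crowd_sizes(bad, 1), "no mass")
})

test_that("config validation rejects degenerate inputs", {
  expect_error(generator_config(crowd_range = c(1, 67)), "lo >= 2")
  expect_error(generator_config(group_size_dist = c(0.5, 0.4)), "sum to 1")
  expect_error(generator_config(within_group_spacing_m = c(2, 1)), "interval")
  expect_error(generator_config(clustering_strength = -1), "nonnegative")
  expect_error(viewshed_spec("c", area_m2 = -5), "positive")
})

test_that("viewshed rectangle reproduces its area", {
  vs <- viewshed_spec("c1", area_m2 = 650, aspect_ratio = 2)
  expect_equal(vs$width_m * vs$height_m, 650, tolerance = 1e-12)
  expect_equal(vs$width_m / vs$height_m, 2, tolerance = 1e-12)
})

test_that("dyad members are separated by the sampled spacing", {
  cfg <- generator_config(group_size_dist = c(0, 1),
                          within_group_spacing_m = c(0.5, 1.0))
  vs <- viewshed_spec("c1")
  dists <- withr::with_seed(5, replicate(200, {
    f <- generate_frame(2, vs, cfg)
    sqrt(diff(f$x_m)^2 + diff(f$y_m)^2)
  }))
  expect_true(all(dists >= 0.5 - 1e-9 & dists <= 1.0 + 1e-9))
})

test_that("frames reject invalid n and over-wide spacing", {
  cfg <- generator_config()
  vs <- viewshed_spec("c1")
  expect_error(generate_frame(1, vs, cfg), "at least 2")
  tiny <- viewshed_spec("c1", area_m2 = 4, aspect_ratio = 1)
  expect_error(withr::with_seed(1, generate_frame(3, tiny, cfg)),
               "too wide")
})

test_that("clustering_strength = 0 with singleton groups gives uniform positions", {
  cfg <- generator_config(clustering_strength = 0,
                          group_size_dist = 1)
  vs <- viewshed_spec("c1")
  pts <- withr::with_seed(11, do.call(rbind, lapply(1:500, function(i) {
    f <- generate_frame(20, vs, cfg, frame_id = sprintf("f%04d", i))
    cbind(f$x_m, f$y_m)
  })))
  expect_gte(stats::ks.test(pts[, 1] / vs$width_m, "punif")$p.value, 0.01)
  expect_gte(stats::ks.test(pts[, 2] / vs$height_m, "punif")$p.value, 0.01)
})

test_that("uniform-limit pair counts match the exact rectangle expectation", {
  cfg <- generator_config(clustering_strength = 0, group_size_dist = 1)
  vs <- viewshed_spec("c1")
  n <- 8
  reps <- 5000
  pairs <- withr::with_seed(13, vapply(seq_len(reps), function(i) {
    f <- generate_frame(n, vs, cfg)
    oracle_count_pairs(f, cfg$threshold_m)
  }, numeric(1)))
  expected <- choose(n, 2) *
    rect_prob_within(cfg$threshold_m, vs$width_m, vs$height_m)
  mc_se <- stats::sd(pairs) / sqrt(reps)
  expect_lte(abs(mean(pairs) - expected), 3 * mc_se)
})

test_that("violation rate increases with clustering strength", {
  rates <- vapply(c(0, 0.6, 1.5), function(cs) {
    cfg <- generator_config(n_cameras = 4, frames_per_camera = 500,
                            clustering_strength = cs, seed = 77L)
    sc <- score_dataset(suppressMessages(filter_frames(
      generate_dataset(cfg))), cfg$threshold_m)
    mean(sc$persons$violation)
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("datasets are complete, in-bounds, and deterministic", {
  cfg <- generator_config(n_cameras = 2, frames_per_camera = 3, seed = 9L)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  key <- paste(d1$camera_id, d1$frame_id)
  expect_length(unique(key), 6L)
  expect_true(all(table(key) >= 2))

  vs <- default_viewsheds(2)
  expect_error(generate_dataset(cfg, vs[c(1, 1), ]), "duplicate")

  study <- default_study()
  vs49 <- default_viewsheds(49)
  expect_true(all(study$detections$x_m >= 0 &
                    study$detections$x_m <= vs49$width_m[1]))
  expect_true(all(study$detections$y_m >= 0 &
                    study$detections$y_m <= vs49$height_m[1]))
  # per-camera crowd-size medians stay in a plausible street range
  sizes <- matrix(attr(study$detections, "crowd_sizes"),
                  nrow = study$config$frames_per_camera)
  med <- apply(sizes, 2, stats::median)
  expect_true(all(med >= 3 & med <= 15))
  # person_id unique within frame
  expect_false(any(duplicated(
    paste(study$detections$camera_id, study$detections$frame_id,
          study$detections$person_id))))
})
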