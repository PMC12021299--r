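# Statistical battery: clustered LPM, frame-level OLS, winsorizing,
# binscatter, per-camera fits, Krippendorff's alpha.

lpm_table <- function(y, x, cluster, camera = "c1") {
  tibble::tibble(camera_id = camera, frame_id = as.character(cluster),
                 violation = y, n_present = x)
}

test_that("clustered LPM recovers the closed-form OLS solution", {
  fit <- fit_lpm_clustered(
    lpm_table(c(0, 1, 0, 1), c(1, 2, 3, 4), c("A", "A", "B", "B")))
  expect_equal(fit$slope, 0.2, tolerance = 1e-12)   # Sxy/Sxx = 1/5
  expect_equal(fit$intercept, 0.0, tolerance = 1e-12)
  expect_equal(fit$n_obs, 4L)
  expect_equal(fit$n_clusters, 2L)
  expect_true(fit$ci_low <= fit$slope && fit$slope <= fit$ci_high)

  const <- fit_lpm_clustered(
    lpm_table(c(1, 1, 1, 1), c(1, 2, 3, 4), c("A", "A", "B", "B")))
  expect_equal(const$slope, 0, tolerance = 1e-12)
  expect_equal(const$se_cluster, 0, tolerance = 1e-12)

  expect_error(fit_lpm_clustered(
    lpm_table(c(0, 1), c(1, 2), c("A", "A"))), "2 clusters")
  expect_error(fit_lpm_clustered(
    lpm_table(c(0, 1), c(3, 3), c("A", "B"))), "constant")
  expect_error(fit_lpm_clustered(
    lpm_table(c(0, 2), c(1, 2), c("A", "B"))), "binary")
})

test_that("cluster-robust SE matches the independent sandwich oracle", {
  withr::with_seed(21, {
    g <- 200
    sizes <- sample(2:12, g, replace = TRUE)
    cl <- rep(sprintf("f%03d", seq_len(g)), sizes)
    n <- length(cl)
    x <- round(stats::runif(n, 2, 40))
    p <- pmin(pmax(0.1 + 0.01 * x + rep(stats::rnorm(g, 0, 0.1), sizes),
                   0), 1)
    y <- stats::rbinom(n, 1, p)
  })
  fit <- fit_lpm_clustered(lpm_table(y, x, cl))
  expect_equal(fit$se_cluster, oracle_cluster_se(y, x, cl),
               tolerance = 1e-10)
  # CR0 drops the small-sample factor exactly
  fit0 <- fit_lpm_clustered(lpm_table(y, x, cl), se_type = "CR0")
  adj <- (g / (g - 1)) * ((n - 1) / (n - 2))
  expect_equal(fit$se_cluster, fit0$se_cluster * sqrt(adj),
               tolerance = 1e-12)
})

test_that("CR1 with singleton clusters equals HC1 from the sandwich package", {
  skip_if_not_installed("sandwich")
  withr::with_seed(31, {
    n <- 150
    x <- round(stats::runif(n, 2, 30))
    y <- stats::rbinom(n, 1, pmin(0.1 + 0.012 * x, 1))
  })
  fit <- fit_lpm_clustered(lpm_table(y, x, sprintf("u%03d", 1:n)))
  lmfit <- stats::lm(y ~ x)
  se_hc1 <- sqrt(sandwich::vcovHC(lmfit, type = "HC1")[2, 2])
  expect_equal(fit$se_cluster, se_hc1, tolerance = 1e-10)
})

test_that("camera fixed effects via demeaning match the dummy regression", {
  withr::with_seed(41, {
    tab <- dplyr::bind_rows(lapply(1:5, function(cam) {
      nf <- 30
      x <- round(stats::runif(nf * 4, 2, 20)) + cam   # camera-shifted crowding
      tibble::tibble(
        camera_id = sprintf("cam%d", cam),
        frame_id = rep(sprintf("f%03d", 1:nf), each = 4),
        n_present = x,
        violation = stats::rbinom(nf * 4, 1,
                                  pmin(0.05 + 0.01 * x + 0.03 * cam, 1)))
    }))
  })
  fe <- fit_lpm_clustered(tab, fixed_effects = "camera")
  dummy <- stats::lm(violation ~ n_present + factor(camera_id), data = tab)
  expect_equal(fe$slope, unname(stats::coef(dummy)["n_present"]),
               tolerance = 1e-10)
  expect_gt(fe$se_cluster, 0)
})

test_that("frame-level OLS matches the normal-equations oracle", {
  perfect <- tibble::tibble(camera_id = "c", frame_id = as.character(1:3),
                            n_present = c(2, 4, 6),
                            n_violators = c(0, 2, 4),
                            n_violating_pairs = c(0, 1, 2))
  fit <- suppressWarnings(fit_frame_ols(perfect))  # exact fit: summary.lm warns
  expect_equal(fit$slope, 1.0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-12)

  withr::with_seed(51, {
    x <- round(stats::runif(10, 2, 30))
    y <- round(0.6 * x + stats::rnorm(10))
  })
  tab <- tibble::tibble(camera_id = "c", frame_id = as.character(1:10),
                        n_present = x, n_violators = y,
                        n_violating_pairs = y)
  fit <- fit_frame_ols(tab)
  sxx <- sum((x - mean(x))^2)
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sxx
  expect_equal(fit$slope, slope_hand, tolerance = 1e-12)
  rss <- sum((y - fit$intercept - fit$slope * x)^2)
  tss <- sum((y - mean(y))^2)
  expect_equal(fit$r_squared, 1 - rss / tss, tolerance = 1e-12)
  # identity: R^2 equals squared correlation of fitted and observed
  expect_equal(fit$r_squared,
               stats::cor(fit$intercept + fit$slope * x, y)^2,
               tolerance = 1e-12)

  expect_error(fit_frame_ols(perfect[1:2, ]), "3 frames")
  same_x <- dplyr::mutate(tab, n_present = 5)
  expect_error(fit_frame_ols(same_x), "variance")
})

test_that("frame-level association on the calibrated dataset is strong and positive", {
  study <- default_study()
  fit <- fit_frame_ols(study$frames)
  expect_gte(fit$slope, 0.4)
  expect_lte(fit$slope, 0.8)
  expect_gt(fit$r_squared, 0.6)
})

test_that("winsorizing caps exactly at the type-7 Tukey outer fence", {
  w <- winsorize_upper(c(1:11, 40))
  expect_equal(w$q3, 9.25, tolerance = 1e-12)
  expect_equal(w$iqr, 5.5, tolerance = 1e-12)
  expect_equal(w$upper_fence, 25.75, tolerance = 1e-12)
  expect_equal(w$n_capped, 1L)
  expect_equal(max(w$values), 25.75, tolerance = 1e-12)
  expect_equal(w$values[1:11], as.numeric(1:11))
  # agrees with the order-statistic oracle
  expect_equal(w$q3, oracle_quantile7(c(1:11, 40), 0.75), tolerance = 1e-12)
  expect_equal(w$q1, oracle_quantile7(c(1:11, 40), 0.25), tolerance = 1e-12)

  vals <- withr::with_seed(3, stats::rpois(50, 5))
  w2 <- winsorize_upper(vals)
  if (w2$n_capped == 0L) expect_identical(w2$values, as.numeric(vals))
  # idempotence
  w3 <- winsorize_upper(w2$values)
  expect_equal(w3$values, w2$values, tolerance = 1e-12)

  expect_error(winsorize_upper(numeric(0)), "empty")
  expect_error(winsorize_upper(c(1, 2, 3)), "4 finite")
})

test_that("binscatter matches the sort-and-chunk oracle", {
  x <- seq(0, 1, length.out = 100)
  bs <- binscatter(x, x, n_bins = 10)
  expect_equal(bs$bin_x_means, bs$bin_y_means, tolerance = 1e-12)
  orc <- oracle_binscatter(x, x, 10)
  expect_equal(bs$bin_x_means, orc$bin_x_means, tolerance = 1e-12)
  expect_equal(bs$bin_counts, orc$bin_counts)

  const <- binscatter(x, rep(3, 100), n_bins = 5)
  expect_true(all(const$bin_y_means == 3))

  one <- binscatter(x, x^2, n_bins = 1)
  expect_equal(one$bin_x_means, mean(x), tolerance = 1e-12)
  expect_equal(one$bin_y_means, mean(x^2), tolerance = 1e-12)

  withr::with_seed(61, {
    xt <- sample(2:15, 300, replace = TRUE)  # heavy ties, like crowd sizes
    yt <- stats::rnorm(300)
  })
  bst <- binscatter(xt, yt, n_bins = 7)
  expect_true(all(diff(bst$bin_x_means) >= 0))
  expect_lte(diff(range(bst$bin_counts)), 1L)
  expect_equal(sum(bst$bin_counts), 300L)

  expect_error(binscatter(c(1, 1, 2), c(1, 2, 3), n_bins = 3), "distinct")
})

test_that("per-camera fits equal fits on manually subset tables", {
  withr::with_seed(71, {
    one_cam <- dplyr::bind_rows(lapply(1:40, function(i) {
      f <- random_frame(sample(3:12, 1), frame_id = sprintf("f%04d", i))
      f
    }))
  })
  sc <- score_dataset(one_cam, 1.5)
  two_cam_p <- dplyr::bind_rows(
    sc$persons, dplyr::mutate(sc$persons, camera_id = "c2"))
  two_cam_f <- dplyr::bind_rows(
    sc$frames, dplyr::mutate(sc$frames, camera_id = "c2"))
  pc <- fit_per_camera(two_cam_p, two_cam_f)
  expect_equal(nrow(pc), 2L)
  expect_equal(pc$lpm_slope[1], pc$lpm_slope[2], tolerance = 1e-12)
  expect_equal(pc$ols_r_squared[1], pc$ols_r_squared[2], tolerance = 1e-12)

  direct <- fit_lpm_clustered(sc$persons)
  expect_equal(pc$lpm_slope[1], direct$slope, tolerance = 1e-12)
  expect_equal(pc$lpm_se[1], direct$se_cluster, tolerance = 1e-12)

  # a camera violating fit preconditions is reported, not silently dropped
  broken_p <- dplyr::mutate(sc$persons, camera_id = "c3", n_present = 5L)
  broken_f <- dplyr::mutate(sc$frames, camera_id = "c3", n_present = 5L)
  pc2 <- suppressMessages(
    fit_per_camera(dplyr::bind_rows(two_cam_p, broken_p),
                   dplyr::bind_rows(two_cam_f, broken_f)))
  expect_equal(nrow(pc2), 2L)
  skipped <- attr(pc2, "skipped")
  expect_equal(skipped$camera_id, "c3")
})

test_that("Krippendorff alpha matches the pooled-variance oracle", {
  perfect <- krippendorff_alpha(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(perfect$alpha, 1.0, tolerance = 1e-12)
  expect_false(perfect$flagged)

  a <- c(1, 2, 3, 4)
  b <- c(1, 2, 3, 5)
  res <- krippendorff_alpha(a, b)
  expect_equal(res$alpha, oracle_alpha_interval(a, b), tolerance = 1e-12)
  expect_lt(res$alpha, 1)

  withr::with_seed(81, {
    aa <- stats::rpois(200, 4)
    bb <- aa + stats::rbinom(200, 1, 0.2) * sample(c(-1, 1), 200, TRUE)
  })
  res2 <- krippendorff_alpha(aa, bb)
  expect_equal(res2$alpha, oracle_alpha_interval(aa, bb), tolerance = 1e-12)

  # ratio level stays within [-?, 1] and equals 1 on identical input
  expect_equal(krippendorff_alpha(aa, aa, "ratio")$alpha, 1,
               tolerance = 1e-12)

  expect_warning(flat <- krippendorff_alpha(c(2, 2, 2), c(2, 2, 2)),
                 "convention")
  expect_equal(flat$alpha, 1)
  expect_true(flat$flagged)
})
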