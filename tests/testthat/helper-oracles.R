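# Independent oracles: deliberately naive implementations (double loops,
# sorting, pooled-variance formulas) against which the package's faster
# code paths are checked.

# O(n^2) neighbour counting by explicit double loop.
oracle_score_frame <- function(frame, threshold_m) {
  n <- nrow(frame)
  nwt <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        dij <- sqrt((frame$x_m[i] - frame$x_m[j])^2 +
                      (frame$y_m[i] - frame$y_m[j])^2)
        if (dij <= threshold_m) nwt[i] <- nwt[i] + 1L
      }
    }
  }
  nwt
}

oracle_count_pairs <- function(frame, threshold_m) {
  n <- nrow(frame)
  cnt <- 0L
  if (n >= 2L) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        dij <- sqrt((frame$x_m[i] - frame$x_m[j])^2 +
                      (frame$y_m[i] - frame$y_m[j])^2)
        if (dij <= threshold_m) cnt <- cnt + 1L
      }
    }
  }
  cnt
}

# Cluster-robust CR1 slope SE by an explicit per-cluster score loop.
oracle_cluster_se <- function(y, x, cluster) {
  X <- cbind(1, x)
  b <- solve(crossprod(X), crossprod(X, y))
  e <- as.numeric(y - X %*% b)
  meat <- matrix(0, 2, 2)
  for (g in unique(cluster)) {
    idx <- cluster == g
    sg <- colSums(X[idx, , drop = FALSE] * e[idx])
    meat <- meat + sg %*% t(sg)
  }
  n <- length(y)
  ng <- length(unique(cluster))
  br <- solve(crossprod(X))
  v <- (ng / (ng - 1)) * ((n - 1) / (n - 2)) * br %*% meat %*% br
  sqrt(v[2, 2])
}

# Type-7 quantile by the textbook order-statistic interpolation.
oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  hh <- (n - 1) * p + 1
  lo <- floor(hh)
  s[lo] + (hh - lo) * (s[min(lo + 1, n)] - s[lo])
}

# Equal-count binning by sort-and-chunk.
oracle_binscatter <- function(x, y, n_bins) {
  ord <- order(x)
  bin <- ceiling(seq_along(ord) * n_bins / length(ord))
  list(
    bin_x_means = as.numeric(tapply(x[ord], bin, mean)),
    bin_y_means = as.numeric(tapply(y[ord], bin, mean)),
    bin_counts = as.integer(table(bin))
  )
}

# Interval-level Krippendorff alpha for two raters from pooled values:
# observed disagreement is the mean squared within-unit difference,
# expected disagreement the mean squared difference over all ordered pairs
# of the 2n pooled ratings.
oracle_alpha_interval <- function(a, b) {
  n <- length(a)
  r <- c(a, b)
  d_obs <- mean((a - b)^2)
  m <- 2 * n
  d_exp <- sum(outer(r, r, function(u, v) (u - v)^2)) / (m * (m - 1))
  1 - d_obs / d_exp
}

# Exact probability that two independent uniform points in a w x h
# rectangle are within distance d (valid for d <= min(w, h)).
rect_prob_within <- function(d, w, h) {
  stopifnot(d <= min(w, h))
  pi * d^2 / (w * h) - 4 * d^3 * (w + h) / (3 * w^2 * h^2) +
    d^4 / (2 * w^2 * h^2)
}

# Random detection frame on a rectangle, for oracle-equivalence fixtures.
random_frame <- function(n, w = 20, h = 10, camera_id = "c1",
                         frame_id = "f0001") {
  tibble::tibble(
    camera_id = camera_id, frame_id = frame_id,
    person_id = sprintf("p%02d", seq_len(n)),
    x_m = stats::runif(n, 0, w), y_m = stats::runif(n, 0, h)
  )
}

# The default calibrated 49-camera dataset, generated and scored once per
# test session and reused across files.
default_study <- function() {
  cached <- getOption("crowdprox.test.study")
  if (!is.null(cached)) return(cached)
  cfg <- crowdprox::generator_config()
  t0 <- proc.time()[["elapsed"]]
  detections <- crowdprox::generate_dataset(cfg)
  gen_secs <- proc.time()[["elapsed"]] - t0
  filtered <- suppressMessages(crowdprox::filter_frames(detections))
  scored <- crowdprox::score_dataset(filtered, cfg$threshold_m)
  res <- list(config = cfg, detections = detections, filtered = filtered,
              persons = scored$persons, frames = scored$frames,
              gen_secs = gen_secs)
  options(crowdprox.test.study = res)
  res
}

# Plain-boundary 650 m2 null curve matching the default study, cached.
default_null_650 <- function() {
  cached <- getOption("crowdprox.test.null650")
  if (!is.null(cached)) return(cached)
  res <- crowdprox::simulate_random_placement(crowdprox::null_model_config(
    area_m2 = 650, aspect_ratio = 2, threshold_m = 1.5,
    n_values = 2:30, replicates = 10000, seed = 915L, boundary = "plain"))
  options(crowdprox.test.null650 = res)
  res
}
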