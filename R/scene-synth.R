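# Synthetic pedestrian-scene generator.
#
# Emulates the statistical structure of hourly surveillance still frames of
# urban street segments: per-frame crowd sizes with an overdispersed,
# right-skewed distribution; pedestrians walking alone or in small companion
# groups (households, dyads); and a tunable tendency of groups to gravitate
# towards one another beyond what uniform placement predicts.

#' Describe a camera viewshed
#'
#' A viewshed is the walkable ground-plane surface visible to one camera,
#' modelled as a rectangle of `area_m2` square meters with width/height ratio
#' `aspect_ratio`.  Coordinates are continuous Cartesian meters with the
#' origin at a rectangle corner.
#'
#' @param camera_id Character label(s), unique per camera.
#' @param area_m2 Walkable surface in square meters (default 650, a typical
#'   inner-city street-segment viewshed).
#' @param aspect_ratio Width divided by height of the bounding rectangle
#'   (default 2: an elongated street segment).
#' @return A tibble with one row per camera and columns `camera_id`,
#'   `area_m2`, `aspect_ratio`, `width_m`, `height_m`.
#' @examples
#' viewshed_spec("cam01")
#' @export
viewshed_spec <- function(camera_id, area_m2 = 650, aspect_ratio = 2) {
  if (any(!is.finite(area_m2)) || any(area_m2 <= 0)) {
    stop("`area_m2` must be positive", call. = FALSE)
  }
  if (any(!is.finite(aspect_ratio)) || any(aspect_ratio <= 0)) {
    stop("`aspect_ratio` must be positive", call. = FALSE)
  }
  tibble::tibble(
    camera_id = as.character(camera_id),
    area_m2 = as.numeric(area_m2),
    aspect_ratio = as.numeric(aspect_ratio),
    width_m = sqrt(area_m2 * aspect_ratio),
    height_m = sqrt(area_m2 / aspect_ratio)
  )
}

#' Build a homogeneous set of viewsheds
#'
#' @param n_cameras Number of cameras.
#' @inheritParams viewshed_spec
#' @return A tibble as returned by [viewshed_spec()].
#' @export
default_viewsheds <- function(n_cameras, area_m2 = 650, aspect_ratio = 2) {
  stopifnot(n_cameras >= 1)
  viewshed_spec(sprintf("cam%02d", seq_len(n_cameras)), area_m2, aspect_ratio)
}

#' Configure the scene generator
#'
#' Defaults are calibrated to the structure of hourly street surveillance
#' footage: per-frame crowd sizes follow a negative binomial (size 1.2, mean
#' 8) truncated to 2--67 persons, which has median 7 and standard deviation
#' 7.7 after truncation; pedestrians walk alone or in companion groups of up
#' to four; companions keep 0.9--2.6 m spacing, straddling the 1.5 m
#' distancing threshold; and group anchor points are drawn by a parent--
#' offspring process whose attraction strength is `clustering_strength`
#' (0 recovers uniform placement).
#'
#' @param n_cameras,frames_per_camera Dataset dimensions.
#' @param crowd_dist Distribution of per-frame person counts before
#'   truncation: a list with `family` one of `"nbinom"` (fields `size`,
#'   `mu`), `"poisson"` (field `lambda`) or `"point"` (field `value`).
#' @param crowd_range Inclusive integer truncation bounds; the lower bound
#'   must be at least 2 (frames with fewer than 2 persons are excluded from
#'   analysis anyway).
#' @param group_size_dist Named or plain probability vector over group sizes
#'   1, 2, ...; must sum to 1.
#' @param within_group_spacing_m Interval (meters) from which the spacing
#'   between adjacent members of a companion group is drawn uniformly.
#' @param clustering_strength Nonnegative attraction knob: each group anchor
#'   after the first is, with probability
#'   `clustering_strength / (1 + clustering_strength)`, scattered around an
#'   earlier anchor (Gaussian, sd `attraction_scale_m`) instead of placed
#'   uniformly.  0 gives uniform anchor placement.
#' @param attraction_scale_m Gaussian scatter (meters) of offspring anchors
#'   around their parent anchor.
#' @param threshold_m Distancing threshold in meters (default 1.5, the Dutch
#'   COVID-19 rule).
#' @param seed Integer root seed; all randomness in [generate_dataset()]
#'   derives deterministic per-frame child streams from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_cameras = 49,
                             frames_per_camera = 100,
                             crowd_dist = list(family = "nbinom",
                                               size = 1.2, mu = 8),
                             crowd_range = c(2L, 67L),
                             group_size_dist = c(0.55, 0.30, 0.10, 0.05),
                             within_group_spacing_m = c(0.9, 2.6),
                             clustering_strength = 0.6,
                             attraction_scale_m = 2.0,
                             threshold_m = 1.5,
                             seed = 2020L) {
  assert_scalar_pos(n_cameras, "n_cameras")
  assert_scalar_pos(frames_per_camera, "frames_per_camera")
  assert_scalar_pos(threshold_m, "threshold_m")
  assert_scalar_pos(attraction_scale_m, "attraction_scale_m")
  if (!is.list(crowd_dist) || is.null(crowd_dist$family)) {
    stop("`crowd_dist` must be a list with a `family` field", call. = FALSE)
  }
  crowd_range <- as.integer(crowd_range)
  if (length(crowd_range) != 2L || crowd_range[1] < 2L ||
        crowd_range[2] < crowd_range[1]) {
    stop("`crowd_range` must be integer bounds c(lo, hi) with lo >= 2",
         call. = FALSE)
  }
  if (any(group_size_dist < 0) ||
        abs(sum(group_size_dist) - 1) > 1e-8) {
    stop("`group_size_dist` must be nonnegative and sum to 1", call. = FALSE)
  }
  if (length(within_group_spacing_m) != 2L ||
        within_group_spacing_m[1] <= 0 ||
        within_group_spacing_m[2] < within_group_spacing_m[1]) {
    stop("`within_group_spacing_m` must be an interval of positive reals",
         call. = FALSE)
  }
  if (!is.numeric(clustering_strength) || clustering_strength < 0) {
    stop("`clustering_strength` must be nonnegative", call. = FALSE)
  }
  structure(
    list(
      n_cameras = as.integer(n_cameras),
      frames_per_camera = as.integer(frames_per_camera),
      crowd_dist = crowd_dist,
      crowd_range = crowd_range,
      group_size_dist = as.numeric(group_size_dist),
      within_group_spacing_m = as.numeric(within_group_spacing_m),
      clustering_strength = as.numeric(clustering_strength),
      attraction_scale_m = as.numeric(attraction_scale_m),
      threshold_m = as.numeric(threshold_m),
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

crowd_pmf <- function(config) {
  x <- seq(config$crowd_range[1], config$crowd_range[2])
  d <- config$crowd_dist
  p <- switch(d$family,
    nbinom  = stats::dnbinom(x, size = d$size, mu = d$mu),
    poisson = stats::dpois(x, lambda = d$lambda),
    point   = as.numeric(x == d$value),
    stop("unknown crowd_dist family: ", d$family, call. = FALSE)
  )
  if (sum(p) < 1e-12) {
    stop("crowd_dist places essentially no mass inside crowd_range",
         call. = FALSE)
  }
  list(x = x, p = p / sum(p))
}

#' Draw per-frame crowd sizes
#'
#' Samples `count` integers from the configured crowd-size distribution,
#' truncated to `crowd_range` by exact renormalisation of the probability
#' mass function.  Uses the current RNG state; callers wanting
#' reproducibility should seed beforehand (as [generate_dataset()] does).
#'
#' @param config A [generator_config()].
#' @param count Number of draws.
#' @return Integer vector of length `count`.
#' @export
sample_crowd_sizes <- function(config, count) {
  stopifnot(inherits(config, "generator_config"), count >= 1)
  pmf <- crowd_pmf(config)
  sample(pmf$x, size = count, replace = TRUE, prob = pmf$p)
}

# Split n persons into companion groups by repeated draws from
# group_size_dist; the last group is trimmed so sizes sum to n exactly.
draw_group_sizes <- function(n, group_size_dist) {
  sizes <- integer(0)
  total <- 0L
  support <- seq_along(group_size_dist)
  while (total < n) {
    s <- sample(support, 1L, prob = group_size_dist)
    s <- min(s, n - total)
    sizes <- c(sizes, s)
    total <- total + s
  }
  sizes
}

# Offsets of k group members around their anchor: members sit on a circle
# whose adjacent-member chord length is drawn uniformly from the spacing
# interval; singletons sit on the anchor.  Returns a k x 2 matrix and the
# circle radius.
group_offsets <- function(k, spacing) {
  if (k == 1L) {
    return(list(offsets = matrix(0, 1L, 2L), radius = 0))
  }
  d <- stats::runif(1L, spacing[1], spacing[2])
  r <- d / (2 * sin(pi / k))
  rot <- stats::runif(1L, 0, 2 * pi)
  ang <- rot + 2 * pi * (seq_len(k) - 1L) / k
  list(offsets = cbind(r * cos(ang), r * sin(ang)), radius = r)
}

#' Generate one synthetic still frame
#'
#' Places `n` pedestrians in the viewshed rectangle.  Persons are partitioned
#' into companion groups; each group's members are arranged around a group
#' anchor with adjacent spacing drawn from `within_group_spacing_m`; anchors
#' are placed by a parent--offspring process (see [generator_config()]).
#' Anchors are confined to an inset rectangle so that every member stays
#' inside the viewshed.  Uses the current RNG state.
#'
#' @param n Number of persons, at least 2.
#' @param viewshed One row of a [viewshed_spec()] tibble.
#' @param config A [generator_config()].
#' @param frame_id Label for the frame (default `"f0001"`).
#' @return A tibble of detections: `camera_id`, `frame_id`, `person_id`,
#'   `x_m`, `y_m`.
#' @export
generate_frame <- function(n, viewshed, config, frame_id = "f0001") {
  stopifnot(inherits(config, "generator_config"))
  if (n < 2) stop("a frame must contain at least 2 persons", call. = FALSE)
  w <- viewshed$width_m[1]
  h <- viewshed$height_m[1]
  spacing <- config$within_group_spacing_m
  # Largest possible member circle: dyads at maximal spacing have radius
  # spacing/2; larger groups have radius d / (2 sin(pi/k)) <= d (k <= 6).
  max_k <- length(config$group_size_dist)
  worst_r <- spacing[2] / (2 * sin(pi / max(2L, max_k)))
  if (2 * worst_r >= min(w, h)) {
    stop("within_group_spacing_m is too wide for the viewshed rectangle",
         call. = FALSE)
  }

  sizes <- draw_group_sizes(n, config$group_size_dist)
  geoms <- lapply(sizes, group_offsets, spacing = spacing)
  p_attract <- config$clustering_strength / (1 + config$clustering_strength)

  anchors <- matrix(NA_real_, length(sizes), 2L)
  for (g in seq_along(sizes)) {
    r <- geoms[[g]]$radius
    lo <- c(r, r)
    hi <- c(w - r, h - r)
    placed <- FALSE
    if (g > 1L && stats::runif(1L) < p_attract) {
      parent <- anchors[sample.int(g - 1L, 1L), ]
      for (try in 1:50) {
        cand <- parent + stats::rnorm(2L, sd = config$attraction_scale_m)
        if (all(cand >= lo) && all(cand <= hi)) {
          anchors[g, ] <- cand
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      anchors[g, ] <- c(stats::runif(1L, lo[1], hi[1]),
                        stats::runif(1L, lo[2], hi[2]))
    }
  }

  xy <- do.call(rbind, lapply(seq_along(sizes), function(g) {
    sweep(geoms[[g]]$offsets, 2L, anchors[g, ], `+`)
  }))
  tibble::tibble(
    camera_id = viewshed$camera_id[1],
    frame_id = frame_id,
    person_id = sprintf("p%02d", seq_len(n)),
    x_m = xy[, 1],
    y_m = xy[, 2]
  )
}

#' Generate a full synthetic detection dataset
#'
#' Produces `n_cameras x frames_per_camera` frames.  Crowd sizes and each
#' frame's placement use deterministic child seeds derived from
#' `config$seed`, so the output is byte-for-byte reproducible and
#' independent of evaluation order.
#'
#' @param config A [generator_config()].
#' @param viewsheds A [viewshed_spec()] tibble with `config$n_cameras` rows
#'   and unique `camera_id`s.
#' @return A detection tibble (`camera_id`, `frame_id`, `person_id`, `x_m`,
#'   `y_m`) with the generated crowd sizes retrievable as
#'   `attr(x, "crowd_sizes")`.
#' @export
generate_dataset <- function(config, viewsheds = default_viewsheds(config$n_cameras)) {
  stopifnot(inherits(config, "generator_config"))
  if (anyDuplicated(viewsheds$camera_id)) {
    stop("duplicate camera_id in viewsheds", call. = FALSE)
  }
  if (nrow(viewsheds) != config$n_cameras) {
    stop("viewsheds must have exactly n_cameras rows", call. = FALSE)
  }
  total <- config$n_cameras * config$frames_per_camera
  sizes <- withr::with_seed(child_seed(config$seed, 0L, stream = 0L),
                            sample_crowd_sizes(config, total))
  frames <- vector("list", total)
  k <- 0L
  for (i in seq_len(config$n_cameras)) {
    vs <- viewsheds[i, ]
    for (j in seq_len(config$frames_per_camera)) {
      k <- k + 1L
      frames[[k]] <- withr::with_seed(
        child_seed(config$seed, k, stream = 1L),
        generate_frame(sizes[k], vs, config,
                       frame_id = sprintf("f%04d", j))
      )
    }
  }
  out <- dplyr::bind_rows(frames)
  attr(out, "crowd_sizes") <- sizes
  out
}

#' Randomly thin a detection table
#'
#' Drops a fraction of detection rows uniformly at random.  Used to emulate
#' an imperfect rater (e.g. a detector that misses pedestrians) in
#' reliability studies; see [krippendorff_alpha()].
#'
#' @param detections A detection table.
#' @param drop_frac Fraction of rows to drop, in `[0, 1)`.
#' @return The thinned detection tibble.
#' @export
thin_detections <- function(detections, drop_frac = 0.1) {
  stopifnot(drop_frac >= 0, drop_frac < 1)
  n <- nrow(detections)
  keep <- sort(sample.int(n, size = round(n * (1 - drop_frac))))
  detections[keep, , drop = FALSE]
}
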