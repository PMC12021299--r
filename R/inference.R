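# Statistical battery: linear probability model with cluster-robust
# standard errors (optionally camera fixed effects), frame-level OLS,
# Tukey outer-fence winsorizing, binned scatterplots, per-camera
# stratified fits.

#' Linear probability model with cluster-robust standard errors
#'
#' Regresses a binary violation indicator on the number of persons present,
#' by closed-form OLS, with persons clustered in still frames.  The slope is
#' the change in violation probability per additional person present.  The
#' cluster-robust variance is the sandwich estimator with CR1 small-sample
#' scaling, `G/(G-1) * (N-1)/(N-k)` (Stata's clustered default); CR0 (no
#' scaling) is available via `se_type`.  Camera fixed effects are absorbed
#' by within-camera demeaning of outcome and predictor, which is exact for
#' the slope; `k` then counts the absorbed means.  Confidence intervals use
#' normal quantiles: with cluster counts in the thousands the difference
#' from t quantiles is negligible.
#'
#' @param person_table Person outcomes (from [score_dataset()]): needs the
#'   outcome column, `n_present`, `camera_id`, `frame_id`.
#' @param outcome Name of the binary outcome column, `"violation"` (>= 1
#'   other within threshold) or `"violation2"` (>= 2 others).
#' @param predictor Name of the crowding predictor column; a pre-winsorized
#'   column may be supplied.
#' @param ci_level Confidence level, e.g. 0.9995 for a test at alpha =
#'   0.0005.
#' @param fixed_effects `"none"` or `"camera"`.
#' @param se_type `"CR1"` (default) or `"CR0"`.
#' @return An object of class `lpm_fit`: slope, intercept, se_cluster,
#'   ci_level, ci_low, ci_high, n_obs, n_clusters, outcome_name,
#'   fixed_effects, se_type.
#' @export
fit_lpm_clustered <- function(person_table,
                              outcome = c("violation", "violation2"),
                              predictor = "n_present",
                              ci_level = 0.9995,
                              fixed_effects = c("none", "camera"),
                              se_type = c("CR1", "CR0")) {
  outcome <- match.arg(outcome)
  fixed_effects <- match.arg(fixed_effects)
  se_type <- match.arg(se_type)
  stopifnot(ci_level > 0, ci_level < 1)
  y <- as.numeric(person_table[[outcome]])
  x <- as.numeric(person_table[[predictor]])
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  cl <- paste(person_table$camera_id, person_table$frame_id, sep = "\r")
  g <- length(unique(cl))
  n <- length(y)
  if (g < 2L) stop("need at least 2 clusters", call. = FALSE)
  if (stats::var(x) == 0) stop("constant predictor", call. = FALSE)

  if (fixed_effects == "camera") {
    cam <- person_table$camera_id
    y_w <- y - stats::ave(y, cam)
    x_w <- x - stats::ave(x, cam)
    if (sum(x_w^2) == 0) {
      stop("predictor constant within cameras", call. = FALSE)
    }
    slope <- sum(x_w * y_w) / sum(x_w^2)
    intercept <- mean(y) - slope * mean(x)  # grand-mean implied
    X <- matrix(x_w, ncol = 1L)
    e <- y_w - x_w * slope
    k_eff <- 1L + length(unique(cam))      # slope + absorbed camera means
    slope_col <- 1L
  } else {
    xb <- mean(x)
    yb <- mean(y)
    sxx <- sum((x - xb)^2)
    slope <- sum((x - xb) * (y - yb)) / sxx
    intercept <- yb - slope * xb
    X <- cbind(1, x)
    e <- y - intercept - slope * x
    k_eff <- 2L
    slope_col <- 2L
  }

  bread <- solve(crossprod(X))
  scores <- rowsum(X * e, cl)              # per-cluster score vectors
  meat <- crossprod(scores)
  adj <- if (se_type == "CR1") {
    g / (g - 1) * (n - 1) / (n - k_eff)
  } else {
    1
  }
  vcov <- adj * bread %*% meat %*% bread
  # a degenerate design can give a true zero variance that lands a hair
  # below zero in floating point
  se <- sqrt(max(vcov[slope_col, slope_col], 0))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  structure(
    list(slope = slope, intercept = intercept, se_cluster = se,
         ci_level = ci_level, ci_low = slope - z * se,
         ci_high = slope + z * se, n_obs = n, n_clusters = g,
         outcome_name = outcome, fixed_effects = fixed_effects,
         se_type = se_type),
    class = "lpm_fit"
  )
}

#' @export
print.lpm_fit <- function(x, ...) {
  cat(sprintf(
    "Linear probability model (%s%s)\n  slope %.5f (cluster-robust %s SE %.5f)\n  %.2f%% CI [%.5f, %.5f]   n = %d persons in %d frames\n",
    x$outcome_name,
    if (x$fixed_effects == "camera") ", camera FE" else "",
    x$slope, x$se_type, x$se_cluster, 100 * x$ci_level,
    x$ci_low, x$ci_high, x$n_obs, x$n_clusters))
  invisible(x)
}

#' Frame-level OLS of violation counts on crowd size
#'
#' @param frame_table Frame summaries (from [score_dataset()]).
#' @param ci_level Confidence level (default 0.995); normal quantiles.
#' @param outcome `"n_violators"` (persons in violation, the default frame-
#'   level outcome) or `"n_violating_pairs"`.
#' @return An object of class `agg_fit`: slope, intercept, se, ci_level,
#'   ci_low, ci_high, r_squared, n_frames.
#' @export
fit_frame_ols <- function(frame_table, ci_level = 0.995,
                          outcome = c("n_violators", "n_violating_pairs")) {
  outcome <- match.arg(outcome)
  stopifnot(ci_level > 0, ci_level < 1)
  if (nrow(frame_table) < 3L) stop("need at least 3 frames", call. = FALSE)
  x <- as.numeric(frame_table$n_present)
  y <- as.numeric(frame_table[[outcome]])
  if (stats::var(x) == 0) {
    stop("no variance in n_present", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  se <- sm$coefficients[2, 2]
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1]), se = se,
         ci_level = ci_level, ci_low = slope - z * se,
         ci_high = slope + z * se, r_squared = sm$r.squared,
         n_frames = nrow(frame_table), outcome_name = outcome),
    class = "agg_fit"
  )
}

#' @export
print.agg_fit <- function(x, ...) {
  cat(sprintf(
    "Frame-level OLS (%s ~ n_present)\n  slope %.4f (SE %.4f), %.1f%% CI [%.4f, %.4f]\n  R-squared %.3f   n = %d frames\n",
    x$outcome_name, x$slope, x$se, 100 * x$ci_level, x$ci_low, x$ci_high,
    x$r_squared, x$n_frames))
  invisible(x)
}

#' Winsorize above the Tukey outer fence
#'
#' Caps values exceeding `Q3 + 3 x IQR` at that fence.  Quartiles use linear
#' interpolation (R's default type-7 quantiles); the fence value depends on
#' this choice, which is therefore fixed.
#'
#' @param values Numeric vector of at least 4 finite values.
#' @return An object of class `winsor_result`: q1, q3, iqr, upper_fence,
#'   n_capped, values (the capped series, original order).
#' @examples
#' winsorize_upper(c(1:11, 40))
#' @export
winsorize_upper <- function(values) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  if (length(values) < 4L || any(!is.finite(values))) {
    stop("need at least 4 finite values", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fence <- q[2] + 3 * iqr
  capped <- pmin(values, fence)
  structure(
    list(q1 = q[1], q3 = q[2], iqr = iqr, upper_fence = fence,
         n_capped = sum(values > fence), values = capped),
    class = "winsor_result"
  )
}

#' @export
print.winsor_result <- function(x, ...) {
  cat(sprintf(
    "Winsorized at the Tukey outer fence: Q3 = %.4g, IQR = %.4g, fence = %.4g\n  %d of %d value(s) capped\n",
    x$q3, x$iqr, x$upper_fence, x$n_capped, length(x$values)))
  invisible(x)
}

#' Binned scatterplot series
#'
#' Assigns observations to `n_bins` equal-count quantile bins of `x` (bin
#' sizes differ by at most one; ties broken by input order) and returns the
#' per-bin means of `x` and `y` in ascending-`x` order.
#'
#' @param x,y Equal-length numeric vectors.
#' @param n_bins Number of bins (default 20); must not exceed the number of
#'   distinct `x` values.
#' @return An object of class `binned_series`: n_bins, bin_x_means,
#'   bin_y_means, bin_counts, n_obs.
#' @export
binscatter <- function(x, y, n_bins = 20) {
  stopifnot(length(x) == length(y), n_bins >= 1)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  if (n_bins > length(unique(x))) {
    stop("n_bins exceeds the number of distinct x values", call. = FALSE)
  }
  bin <- ceiling(rank(x, ties.method = "first") * n_bins / length(x))
  structure(
    list(
      n_bins = as.integer(n_bins),
      bin_x_means = as.numeric(tapply(x, bin, mean)),
      bin_y_means = as.numeric(tapply(y, bin, mean)),
      bin_counts = as.integer(tabulate(bin, nbins = n_bins)),
      n_obs = length(x)
    ),
    class = "binned_series"
  )
}

#' @export
print.binned_series <- function(x, ...) {
  cat(sprintf("Binned series: %d bins over %d observations\n",
              x$n_bins, x$n_obs))
  print(tibble::tibble(bin_x_mean = x$bin_x_means,
                       bin_y_mean = x$bin_y_means,
                       n = x$bin_counts))
  invisible(x)
}

#' Convert a binned series to a tibble
#' @param x A `binned_series`.
#' @return A tibble with `bin_x_mean`, `bin_y_mean`, `n`.
#' @export
as_tibble_binned <- function(x) {
  stopifnot(inherits(x, "binned_series"))
  tibble::tibble(bin_x_mean = x$bin_x_means, bin_y_mean = x$bin_y_means,
                 n = x$bin_counts)
}

#' Stratified per-camera fits
#'
#' Re-runs the person-level clustered LPM and the frame-level OLS within
#' every camera.  Cameras whose data violate a fit's preconditions (too few
#' frames, constant predictor) are reported in the `skipped` attribute, not
#' silently dropped.
#'
#' @param person_table,frame_table Tables from [score_dataset()].
#' @param ci_level_person,ci_level_frame Confidence levels for the two fits.
#' @param outcome Outcome for the person-level fit.
#' @return A tibble with one row per successfully fitted camera: camera_id,
#'   lpm_slope, lpm_se, lpm_ci_low, lpm_ci_high, lpm_n, lpm_clusters,
#'   ols_slope, ols_se, ols_r_squared, ols_n_frames.  Attribute `skipped`:
#'   a tibble of (camera_id, stage, message) for failures.
#' @export
fit_per_camera <- function(person_table, frame_table,
                           ci_level_person = 0.9995,
                           ci_level_frame = 0.995,
                           outcome = "violation") {
  cams <- unique(person_table$camera_id)
  rows <- list()
  skipped <- list()
  for (cam in cams) {
    pt <- person_table[person_table$camera_id == cam, , drop = FALSE]
    ft <- frame_table[frame_table$camera_id == cam, , drop = FALSE]
    lpm <- tryCatch(
      fit_lpm_clustered(pt, outcome = outcome, ci_level = ci_level_person),
      error = function(e) e)
    ols <- tryCatch(
      fit_frame_ols(ft, ci_level = ci_level_frame),
      error = function(e) e)
    if (inherits(lpm, "error")) {
      skipped[[length(skipped) + 1L]] <-
        tibble::tibble(camera_id = cam, stage = "lpm",
                       message = conditionMessage(lpm))
      next
    }
    if (inherits(ols, "error")) {
      skipped[[length(skipped) + 1L]] <-
        tibble::tibble(camera_id = cam, stage = "frame_ols",
                       message = conditionMessage(ols))
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      camera_id = cam,
      lpm_slope = lpm$slope, lpm_se = lpm$se_cluster,
      lpm_ci_low = lpm$ci_low, lpm_ci_high = lpm$ci_high,
      lpm_n = lpm$n_obs, lpm_clusters = lpm$n_clusters,
      ols_slope = ols$slope, ols_se = ols$se,
      ols_r_squared = ols$r_squared, ols_n_frames = ols$n_frames
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  if (length(skipped)) {
    message(sprintf("fit_per_camera: %d camera(s) skipped (see attr 'skipped')",
                    length(skipped)))
  }
  out
}
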