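# Inter-rater reliability for violation counts.

#' Krippendorff's alpha for two raters
#'
#' Chance-corrected agreement between two aligned rating vectors (here:
#' per-frame violation counts from two scorers), computed exactly from the
#' coincidence matrix: `alpha = 1 - D_observed / D_expected`.  At the
#' interval level the difference function is the squared difference of the
#' rated values; at the ratio level it is the squared relative difference
#' `((c - k) / (c + k))^2`.
#'
#' @param ratings_a,ratings_b Numeric vectors of equal length (>= 2 units);
#'   units with a missing value in either vector are dropped with a message.
#' @param metric_level `"interval"` (default, appropriate for counts) or
#'   `"ratio"`.
#' @return An object of class `reliability_result`: alpha, metric_level,
#'   n_units, d_observed, d_expected, flagged (TRUE when expected
#'   disagreement is zero and alpha = 1 is returned by convention).
#' @examples
#' krippendorff_alpha(c(1, 2, 3, 4), c(1, 2, 3, 5))
#' @export
krippendorff_alpha <- function(ratings_a, ratings_b,
                               metric_level = c("interval", "ratio")) {
  metric_level <- match.arg(metric_level)
  stopifnot(length(ratings_a) == length(ratings_b))
  ok <- is.finite(ratings_a) & is.finite(ratings_b)
  if (!all(ok)) {
    message(sprintf("krippendorff_alpha: dropping %d unpairable unit(s)",
                    sum(!ok)))
  }
  a <- ratings_a[ok]
  b <- ratings_b[ok]
  n_units <- length(a)
  if (n_units < 2L) stop("need at least 2 pairable units", call. = FALSE)

  vals <- sort(unique(c(a, b)))
  m <- length(vals)
  ia <- match(a, vals)
  ib <- match(b, vals)
  # Coincidence matrix: each unit has 2 ratings, hence 2 ordered pairs with
  # weight 1/(m_u - 1) = 1.
  o <- matrix(0, m, m)
  for (u in seq_len(n_units)) {
    o[ia[u], ib[u]] <- o[ia[u], ib[u]] + 1
    o[ib[u], ia[u]] <- o[ib[u], ia[u]] + 1
  }
  n_c <- rowSums(o)
  n_tot <- sum(n_c)
  delta2 <- switch(metric_level,
    interval = outer(vals, vals, function(c, k) (c - k)^2),
    ratio = outer(vals, vals, function(c, k) {
      s <- c + k
      ifelse(s == 0, 0, ((c - k) / s)^2)
    })
  )
  d_obs <- sum(o * delta2) / n_tot
  d_exp <- sum(outer(n_c, n_c) * delta2) / (n_tot * (n_tot - 1))
  flagged <- d_exp == 0
  alpha <- if (flagged) 1 else 1 - d_obs / d_exp
  if (flagged) {
    warning("all ratings identical: expected disagreement is zero; ",
            "returning alpha = 1 by convention", call. = FALSE)
  }
  structure(
    list(alpha = alpha, metric_level = metric_level, n_units = n_units,
         d_observed = d_obs, d_expected = d_exp, flagged = flagged),
    class = "reliability_result"
  )
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("Krippendorff's alpha (%s level): %.4f over %d units%s\n",
              x$metric_level, x$alpha, x$n_units,
              if (x$flagged) " [degenerate: no expected disagreement]" else ""))
  invisible(x)
}

#' Agreement between the scorer and a degraded scorer
#'
#' Mirrors a human-vs-machine validation design: scores the same detection
#' dataset twice -- once in full and once after randomly dropping a fraction
#' of detections (an imperfect rater) -- and computes Krippendorff's alpha
#' on the per-frame violator counts of the frames both raters could score.
#'
#' @param detections A filtered detection table.
#' @param threshold_m Distance threshold in meters.
#' @param drop_frac Fraction of detections the degraded rater misses.
#' @param seed Seed for the thinning.
#' @return A `reliability_result` (see [krippendorff_alpha()]).
#' @export
scorer_agreement <- function(detections, threshold_m = 1.5,
                             drop_frac = 0.1, seed = 1L) {
  full <- score_dataset(detections, threshold_m)$frames
  thinned <- withr::with_seed(seed, thin_detections(detections, drop_frac))
  thinned <- suppressMessages(filter_frames(thinned))
  degraded <- score_dataset(thinned, threshold_m)$frames
  merged <- dplyr::inner_join(
    full, degraded,
    by = c("camera_id", "frame_id"), suffix = c("_full", "_degraded"))
  krippendorff_alpha(merged$n_violators_full, merged$n_violators_degraded,
                     metric_level = "interval")
}
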