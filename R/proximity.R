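# Proximity scoring: per-person neighbour counts within the distancing
# threshold, binary violation indicators, and per-frame aggregates.
#
# The normative definition is the brute-force pairwise Euclidean distance in
# the ground plane; a person violates distancing when at least one other
# person is at distance <= threshold ("within a radius" read as a closed
# ball).  The stricter `violation2` indicator (>= 2 others within the
# threshold) proxies encounters beyond a single walking companion.

#' Drop frames with fewer than two persons
#'
#' A person alone in a frame cannot be involved in a close encounter, so
#' such frames carry no information about distancing behaviour and are
#' excluded before scoring.
#'
#' @param detections A detection table (`camera_id`, `frame_id`,
#'   `person_id`, `x_m`, `y_m`).  Rows with missing coordinates are an
#'   error, never silently dropped.
#' @return The filtered tibble; the number of dropped frames is attached as
#'   `attr(x, "frames_dropped")` and reported via `message()`.
#' @export
filter_frames <- function(detections) {
  assert_detection_table(detections)
  if (nrow(detections) == 0L) {
    attr(detections, "frames_dropped") <- 0L
    return(detections)
  }
  key <- frame_key(detections)
  sizes <- table(key)
  keep <- key %in% names(sizes)[sizes >= 2L]
  dropped <- sum(sizes < 2L)
  out <- detections[keep, , drop = FALSE]
  attr(out, "frames_dropped") <- as.integer(dropped)
  message(sprintf("filter_frames: dropped %d frame(s) with < 2 persons",
                  dropped))
  out
}

#' Score one frame
#'
#' Counts, for every person, the other persons at Euclidean distance at most
#' `threshold_m`, and derives the violation indicators.
#'
#' @param frame Detections of a single frame (>= 2 rows, one
#'   `camera_id`/`frame_id`).
#' @param threshold_m Positive distance threshold in meters.
#' @return A tibble with one row per person: `camera_id`, `frame_id`,
#'   `person_id`, `n_present`, `n_within_threshold`, `violation`,
#'   `violation2`.
#' @examples
#' f <- tibble::tibble(camera_id = "c", frame_id = "f",
#'                     person_id = c("a", "b", "c"),
#'                     x_m = c(0, 1.4, 2.8), y_m = 0)
#' score_frame(f, 1.5)
#' @export
score_frame <- function(frame, threshold_m) {
  assert_scalar_pos(threshold_m, "threshold_m")
  assert_detection_table(frame)
  n <- nrow(frame)
  if (n < 2L) stop("a frame must have at least 2 detections", call. = FALSE)
  if (length(unique(frame$camera_id)) != 1L ||
        length(unique(frame$frame_id)) != 1L) {
    stop("score_frame() expects detections from a single frame",
         call. = FALSE)
  }
  if (anyDuplicated(frame$person_id)) {
    stop("person_id must be unique within a frame", call. = FALSE)
  }
  d <- as.matrix(stats::dist(cbind(frame$x_m, frame$y_m)))
  nwt <- as.integer(rowSums(d <= threshold_m) - 1L)
  tibble::tibble(
    camera_id = frame$camera_id,
    frame_id = frame$frame_id,
    person_id = frame$person_id,
    n_present = n,
    n_within_threshold = nwt,
    violation = as.integer(nwt >= 1L),
    violation2 = as.integer(nwt >= 2L)
  )
}

#' Aggregate person outcomes to a frame summary
#'
#' `n_violating_pairs` is recovered from the symmetry identity
#' sum(n_within_threshold) = 2 x (number of violating pairs); an explicit
#' vector of pairwise distances may be supplied for cross-validation.
#'
#' @param outcomes Person outcomes of a single frame (from [score_frame()]).
#' @param pair_distances Optional numeric vector of the frame's unordered
#'   pairwise distances (e.g. `stats::dist(...)`), checked against the
#'   outcome-derived pair count.
#' @param threshold_m Threshold used when `pair_distances` is supplied.
#' @return A one-row tibble: `camera_id`, `frame_id`, `n_present`,
#'   `n_violators`, `n_violating_pairs`.
#' @export
summarize_frame <- function(outcomes, pair_distances = NULL,
                            threshold_m = NULL) {
  if (length(unique(paste(outcomes$camera_id, outcomes$frame_id))) != 1L) {
    stop("summarize_frame() expects outcomes from a single frame",
         call. = FALSE)
  }
  total <- sum(outcomes$n_within_threshold)
  stopifnot(total %% 2L == 0L)
  pairs <- total %/% 2L
  if (!is.null(pair_distances)) {
    stopifnot(!is.null(threshold_m))
    direct <- sum(pair_distances <= threshold_m)
    if (direct != pairs) {
      stop("pair_distances disagree with the outcome-derived pair count",
           call. = FALSE)
    }
  }
  tibble::tibble(
    camera_id = outcomes$camera_id[1],
    frame_id = outcomes$frame_id[1],
    n_present = outcomes$n_present[1],
    n_violators = sum(outcomes$violation),
    n_violating_pairs = as.integer(pairs)
  )
}

#' Score a whole detection dataset
#'
#' @param detections A detection table that already passed
#'   [filter_frames()]; a frame with fewer than 2 persons is an error.
#' @param threshold_m Positive distance threshold in meters (default 1.5).
#' @return A list with `persons` (one row per detection) and `frames` (one
#'   row per frame), as produced by [score_frame()] and
#'   [summarize_frame()].
#' @export
score_dataset <- function(detections, threshold_m = 1.5) {
  assert_detection_table(detections)
  key <- frame_key(detections)
  groups <- split(seq_len(nrow(detections)), key)
  if (any(lengths(groups) < 2L)) {
    stop("input contains frames with < 2 persons; run filter_frames() first",
         call. = FALSE)
  }
  # preserve first-appearance frame order
  groups <- groups[unique(key)]
  person_list <- vector("list", length(groups))
  frame_list <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    out <- score_frame(detections[groups[[i]], , drop = FALSE], threshold_m)
    person_list[[i]] <- out
    frame_list[[i]] <- summarize_frame(out)
  }
  persons <- dplyr::bind_rows(person_list)
  stopifnot(nrow(persons) == nrow(detections))
  list(persons = persons, frames = dplyr::bind_rows(frame_list))
}
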