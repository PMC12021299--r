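# Internal helpers: seed streams, validation, logging.

# Deterministic child seed for a (root seed, stream, index) triple.  All
# arithmetic stays below 2^53 so the modulo is exact in doubles; results fit
# in a 32-bit integer as required by set.seed().
child_seed <- function(seed, index, stream = 0L) {
  s <- as.numeric(seed) %% 2097143
  as.integer((s * 1013 + as.numeric(stream) * 7919 +
                as.numeric(index) * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

detection_cols <- c("camera_id", "frame_id", "person_id", "x_m", "y_m")

assert_detection_table <- function(detections) {
  missing <- setdiff(detection_cols, names(detections))
  if (length(missing)) {
    stop("detection table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- !is.finite(detections$x_m) | !is.finite(detections$y_m)
  if (any(bad)) {
    stop(sum(bad), " detection row(s) have missing or non-finite coordinates",
         call. = FALSE)
  }
  invisible(detections)
}

frame_key <- function(tab) paste(tab$camera_id, tab$frame_id, sep = "\r")

log_levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)

pipe_log <- function(level, msg, threshold = "info") {
  if (log_levels[[level]] >= log_levels[[threshold]]) {
    message(sprintf("[%s] %s", level, msg))
  }
  invisible(NULL)
}
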