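#' Dynamic PET frame schedule
#'
#' A frame schedule is a set of contiguous, non-overlapping acquisition frames
#' described by their start times and durations in seconds. The default is the
#' 19-frame dynamic protocol used throughout the package:
#' 1 x 15, 3 x 5, 3 x 10, 4 x 60, 2 x 150, 2 x 60 and 4 x 600 s frames.
#' The protocol frame list sums to 52 min while the acquisition itself runs
#' 60 min; `extend_last` stretches the final frame so the schedule closes the
#' 60-min span (needed for 30-60 min uptake windows).
#'
#' @param durations_s frame durations in seconds, in acquisition order.
#' @param extend_last logical; extend the last frame so total span is
#'   `target_span_min` minutes.
#' @param target_span_min total span (minutes) used when `extend_last = TRUE`.
#' @return An object of class `frame_schedule`: a data.frame with columns
#'   `start_s`, `dur_s`, `mid_s` (frame midpoint).
#' @examples
#' sch <- frame_schedule()
#' sum(sch$dur_s) / 60  # 52 minutes as acquired
#' sch60 <- frame_schedule(extend_last = TRUE)
#' sum(sch60$dur_s) / 60
#' @export
frame_schedule <- function(durations_s = default_frame_durations(),
                           extend_last = FALSE,
                           target_span_min = 60) {
  if (!is.numeric(durations_s) || length(durations_s) < 1L ||
      any(!is.finite(durations_s)) || any(durations_s <= 0)) {
    stop("`durations_s` must be a vector of strictly positive frame durations")
  }
  durations_s <- as.numeric(durations_s)
  if (extend_last) {
    gap <- target_span_min * 60 - sum(durations_s)
    if (gap < 0) stop("schedule already longer than `target_span_min`")
    durations_s[length(durations_s)] <- durations_s[length(durations_s)] + gap
  }
  start_s <- cumsum(c(0, durations_s[-length(durations_s)]))
  out <- data.frame(start_s = start_s, dur_s = durations_s,
                    mid_s = start_s + durations_s / 2)
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' @rdname frame_schedule
#' @export
default_frame_durations <- function() {
  c(rep(15, 1), rep(5, 3), rep(10, 3), rep(60, 4),
    rep(150, 2), rep(60, 2), rep(600, 4))
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, span %.1f min\n",
              nrow(x), sum(x$dur_s) / 60))
  invisible(x)
}

schedule_span_min <- function(schedule) {
  (schedule$start_s[nrow(schedule)] + schedule$dur_s[nrow(schedule)]) / 60
}

assert_frame_schedule <- function(schedule) {
  if (!inherits(schedule, "frame_schedule")) {
    if (is.data.frame(schedule) && all(c("start_s", "dur_s") %in% names(schedule))) {
      schedule$mid_s <- schedule$start_s + schedule$dur_s / 2
      class(schedule) <- c("frame_schedule", "data.frame")
    } else {
      stop("`schedule` must be a frame_schedule (see `frame_schedule()`)")
    }
  }
  ends <- schedule$start_s + schedule$dur_s
  if (any(schedule$dur_s <= 0)) stop("frame durations must be positive")
  if (nrow(schedule) > 1 &&
      any(abs(schedule$start_s[-1] - ends[-nrow(schedule)]) > 1e-6)) {
    stop("frames must be contiguous and non-overlapping")
  }
  schedule
}
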