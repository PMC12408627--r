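#' Regional time-activity curve
#'
#' Frame-wise radioactivity concentration (kBq/mL, decay-corrected) in a
#' region of interest, tied to a [frame_schedule()].
#'
#' @param schedule a `frame_schedule`.
#' @param activity numeric vector of activity concentrations (kBq/mL), one
#'   per frame.
#' @param region region label (e.g. `"neuroforamina"`).
#' @param session session label (e.g. `"test"` or `"retest"`).
#' @param subject subject label.
#' @return An object of class `tac`: a list with elements `schedule`,
#'   `activity`, `region`, `session`, `subject`.
#' @examples
#' sch <- frame_schedule()
#' tac <- new_tac(sch, seq_len(nrow(sch)))
#' tac_midpoints_min(tac)[1:4]
#' @export
new_tac <- function(schedule, activity, region = "region",
                    session = "test", subject = "s01") {
  schedule <- assert_frame_schedule(schedule)
  activity <- as.numeric(activity)
  if (length(activity) != nrow(schedule)) {
    stop(sprintf("activity has %d values but schedule has %d frames",
                 length(activity), nrow(schedule)))
  }
  if (any(!is.finite(activity))) stop("activity must be finite")
  structure(list(schedule = schedule, activity = activity,
                 region = region, session = session, subject = subject),
            class = "tac")
}

#' @rdname new_tac
#' @export
tac_midpoints_min <- function(tac) tac$schedule$mid_s / 60

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %s/%s/%s: %d frames, span %.1f min, peak %.2f kBq/mL\n",
              x$subject, x$region, x$session, length(x$activity),
              schedule_span_min(x$schedule), max(x$activity)))
  invisible(x)
}

# Piecewise-linear interpolation of frame values at midpoints, anchored at
# (0, 0): dynamic scans start at injection with no activity in tissue.
# Returns activity on an arbitrary time grid (minutes).
tac_interp <- function(tac, t_min) {
  mids <- tac_midpoints_min(tac)
  stats::approx(x = c(0, mids), y = c(0, tac$activity), xout = t_min,
                rule = 2)$y
}

# Time-weighted mean activity over a [t0, t1] window (minutes), by trapezoid
# on a 1-s grid over the interpolated curve.
tac_window_mean <- function(tac, window_min) {
  span <- schedule_span_min(tac$schedule)
  if (window_min[1] < 0 || window_min[2] > span + 1e-9) {
    stop(sprintf("window [%g, %g] min outside TAC span [0, %g] min",
                 window_min[1], window_min[2], span))
  }
  tt <- seq(window_min[1], window_min[2], by = 1 / 60)
  y <- tac_interp(tac, tt)
  trapz(tt, y) / (window_min[2] - window_min[1])
}

trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Read and write TAC tables
#'
#' The on-disk TAC format is a CSV with columns `frame_start_s`,
#' `frame_duration_s`, `activity_kbq_ml`, `region`, `session`, `subject`
#' (times in seconds on disk, minutes at the API surface).
#'
#' @param tacs a list of `tac` objects (or a single one).
#' @param path file path.
#' @return `read_tac_csv()` returns a list of `tac` objects.
#' @export
write_tac_csv <- function(tacs, path) {
  if (inherits(tacs, "tac")) tacs <- list(tacs)
  rows <- do.call(rbind, lapply(tacs, function(x) {
    data.frame(frame_start_s = x$schedule$start_s,
               frame_duration_s = x$schedule$dur_s,
               activity_kbq_ml = x$activity,
               region = x$region, session = x$session, subject = x$subject)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac_csv
#' @export
read_tac_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_start_s", "frame_duration_s", "activity_kbq_ml",
            "region", "session", "subject")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("TAC file '%s' is missing column(s): %s",
                 path, paste(miss, collapse = ", ")))
  }
  bad <- which(!is.finite(df$activity_kbq_ml) | df$activity_kbq_ml < 0)
  if (length(bad)) {
    stop(sprintf("TAC file '%s': non-finite or negative activity at row %d",
                 path, bad[1]))
  }
  key <- interaction(df$subject, df$region, df$session, drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$frame_start_s), ]
    sch <- frame_schedule(d$frame_duration_s)
    if (max(abs(sch$start_s - d$frame_start_s)) > 1e-6) {
      stop(sprintf("TAC file '%s': frames for %s/%s/%s are not contiguous",
                   path, d$subject[1], d$region[1], d$session[1]))
    }
    new_tac(sch, d$activity_kbq_ml, region = d$region[1],
            session = d$session[1], subject = d$subject[1])
  })
}
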