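#' Frame schedule for dynamic PET
#'
#' A frame schedule records the start time and duration of every acquisition
#' frame of a dynamic PET scan, in seconds. Frames must be contiguous,
#' non-overlapping and strictly increasing. Frame mid-times (in minutes) are
#' derived and used as the time variable throughout the kinetic modelling.
#'
#' @param frame_start numeric vector of frame start times (seconds).
#' @param frame_duration numeric vector of frame durations (seconds).
#' @return An object of class `frame_schedule` with elements `start`,
#'   `duration` (seconds) and `mid_min` (frame mid-times, minutes).
#' @seealso [default_frame_schedule()]
#' @export
frame_schedule <- function(frame_start, frame_duration) {
  frame_start <- as.numeric(frame_start)
  frame_duration <- as.numeric(frame_duration)
  if (length(frame_start) == 0L)
    stop("frame schedule must contain at least one frame")
  if (length(frame_start) != length(frame_duration))
    stop("frame_start and frame_duration must have equal length")
  if (any(frame_duration <= 0))
    stop("frame durations must be positive")
  if (is.unsorted(frame_start, strictly = TRUE))
    stop("frame start times must be strictly increasing")
  ends <- frame_start + frame_duration
  if (any(abs(frame_start[-1] - ends[-length(ends)]) > 1e-9))
    stop("frames must be contiguous (each frame starts where the last ends)")
  structure(
    list(start = frame_start, duration = frame_duration,
         mid_min = (frame_start + frame_duration / 2) / 60),
    class = "frame_schedule"
  )
}

#' Default 30-frame, 90-minute acquisition schedule
#'
#' Four 15 s, four 30 s, three 1 min, two 2 min, five 4 min and twelve 5 min
#' frames: 30 frames spanning 90 minutes in total, the standard re-binning
#' used for dynamic PiB acquisitions.
#'
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  dur <- c(rep(15, 4), rep(30, 4), rep(60, 3), rep(120, 2),
           rep(240, 5), rep(300, 12))
  frame_schedule(cumsum(c(0, dur[-length(dur)])), dur)
}

#' @export
length.frame_schedule <- function(x) length(x$start)

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %.1f min total\n",
              length(x), sum(x$duration) / 60))
  invisible(x)
}

#' Time-activity curve
#'
#' Mean radioactivity concentration per acquisition frame (arbitrary scale,
#' conventionally kBq/mL) on a given [frame_schedule()].
#'
#' @param schedule a [frame_schedule()].
#' @param activity numeric vector, one value per frame.
#' @return An object of class `tac`.
#' @export
tac <- function(schedule, activity) {
  if (!inherits(schedule, "frame_schedule"))
    stop("schedule must be a frame_schedule")
  activity <- as.numeric(activity)
  if (length(activity) != length(schedule))
    stop("activity length must match the number of frames")
  if (any(!is.finite(activity)))
    stop("activity values must be finite")
  structure(list(schedule = schedule, activity = activity), class = "tac")
}

#' @export
length.tac <- function(x) length(x$activity)

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %d frames, peak %.3g at %.1f min\n", length(x),
              max(x$activity), x$schedule$mid_min[which.max(x$activity)]))
  invisible(x)
}

stopifnot_same_schedule <- function(a, b) {
  sa <- a$schedule; sb <- b$schedule
  if (length(sa) != length(sb) ||
      max(abs(sa$start - sb$start)) > 1e-9 ||
      max(abs(sa$duration - sb$duration)) > 1e-9)
    stop("time-activity curves are on different frame schedules")
  invisible(TRUE)
}
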