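#' Frame schedule of a dynamic PET acquisition
#'
#' A frame schedule records, for every time frame, its start time and
#' duration in seconds. Frames must be contiguous (each frame starts where
#' the previous one ends), non-overlapping, and start at time zero --
#' the histogramming convention of small-animal FDG protocols.
#'
#' @param durations_s numeric vector of frame durations in seconds, all > 0.
#' @param start_times_s optional numeric vector of frame start times in
#'   seconds. If omitted, frames are laid out contiguously from 0. If given,
#'   it must satisfy `start[i+1] == start[i] + durations[i]` and `start[1] == 0`.
#' @return An object of class `frame_schedule` with fields `start_s`,
#'   `duration_s`, `mid_s` (frame mid-times) and `end_s`.
#' @examples
#' sched <- fdg_frame_schedule()    # 12x30 s, 3x60 s, 3x120 s, 7x240 s
#' length(sched$start_s)            # 25 frames
#' max(sched$end_s)                 # 2580 s total
#' @export
frame_schedule <- function(durations_s, start_times_s = NULL) {
  durations_s <- as.numeric(durations_s)
  if (length(durations_s) == 0L)
    stop("frame schedule must contain at least one frame")
  if (any(!is.finite(durations_s)) || any(durations_s <= 0))
    stop("frame durations must be finite and strictly positive")
  contiguous <- cumsum(c(0, durations_s[-length(durations_s)]))
  if (is.null(start_times_s)) {
    start_times_s <- contiguous
  } else {
    start_times_s <- as.numeric(start_times_s)
    if (length(start_times_s) != length(durations_s))
      stop("start_times_s and durations_s must have equal length")
    if (abs(start_times_s[1]) > 1e-9)
      stop("first frame must start at time 0, got ", start_times_s[1])
    if (any(abs(start_times_s - contiguous) > 1e-6))
      stop("frames must be contiguous and non-overlapping: ",
           "start[i+1] must equal start[i] + duration[i]")
  }
  structure(
    list(start_s = start_times_s,
         duration_s = durations_s,
         mid_s = start_times_s + durations_s / 2,
         end_s = start_times_s + durations_s),
    class = "frame_schedule")
}

#' Default dynamic FDG frame schedule
#'
#' The 45-minute framing used throughout this package: 12 frames of 30 s,
#' 3 of 60 s, 3 of 120 s and 7 of 240 s (25 frames, 2580 s total).
#'
#' @return A [frame_schedule()].
#' @export
fdg_frame_schedule <- function() {
  frame_schedule(c(rep(30, 12), rep(60, 3), rep(120, 3), rep(240, 7)))
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat("Frame schedule:", length(x$start_s), "frames,",
      max(x$end_s), "s total\n")
  tab <- rle(x$duration_s)
  cat("  ", paste(sprintf("%dx%gs", tab$lengths, tab$values), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.frame_schedule <- function(x) length(x$start_s)

#' Read / write a frame schedule as CSV
#'
#' The on-disk form is a comma-separated table with header
#' `frame,start_s,duration_s`, one row per frame.
#'
#' @param path file path.
#' @param schedule a [frame_schedule()].
#' @return `read_frame_schedule` returns a `frame_schedule`;
#'   `write_frame_schedule` returns `path` invisibly.
#' @export
read_frame_schedule <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("frame", "start_s", "duration_s")
  if (!all(need %in% names(tab)))
    stop("schedule file must have columns ", paste(need, collapse = ", "))
  tab <- tab[order(tab$frame), , drop = FALSE]
  frame_schedule(tab$duration_s, tab$start_s)
}

#' @rdname read_frame_schedule
#' @export
write_frame_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "frame_schedule"))
  utils::write.csv(
    data.frame(frame = seq_along(schedule$start_s),
               start_s = schedule$start_s,
               duration_s = schedule$duration_s),
    path, row.names = FALSE)
  invisible(path)
}
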