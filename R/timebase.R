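#' Frame/time coordinate model
#'
#' Frames are half-open intervals: frame `i` (0-based) covers
#' `[i * frame_period, (i + 1) * frame_period)` seconds. At the standard
#' acquisition rate of 12.5 Hz one double frame lasts 80 ms, so odor onset at
#' 4 s corresponds to frame 50, and the 81--160 ms post-onset analysis window
#' is exactly the second post-onset frame (relative index 1).
#'
#' @param t Time in seconds (scalar or vector).
#' @param frame_period Frame duration in seconds.
#' @param n_frames Total number of frames; used for range checking.
#' @return `frame_of_time()`: 0-based frame indices. `time_of_frame()`: the
#'   start time (seconds) of each frame.
#' @examples
#' frame_of_time(4.0, 0.08, 200)  # 50
#' time_of_frame(50, 0.08)        # 4
#' @export
frame_of_time <- function(t, frame_period, n_frames) {
  check_scalar_number(frame_period, "frame_period", min = 0, strict_min = TRUE)
  check_count(n_frames, "n_frames")
  if (any(!is.finite(t)) || any(t < 0) || any(t > n_frames * frame_period + 1e-12)) {
    stop_glomsep("time out of range [0, %s] s", format(n_frames * frame_period))
  }
  i <- floor(t / frame_period + 1e-9)
  # t exactly at the end of the recording belongs to the last frame
  pmin(as.integer(i), n_frames - 1L)
}

#' @rdname frame_of_time
#' @param i 0-based frame index (scalar or vector).
#' @export
time_of_frame <- function(i, frame_period) {
  check_scalar_number(frame_period, "frame_period", min = 0, strict_min = TRUE)
  if (any(i != round(i)) || any(i < 0)) stop_glomsep("frame index must be a non-negative integer")
  i * frame_period
}

# Post-onset relative frame indices whose half-open intervals lie inside
# [lo, hi) seconds after odor onset. With frame_period = 0.08 the window
# [0.08, 0.16) is relative frame 1; [0, 0.16) is frames {0, 1}.
window_rel_frames <- function(lo, hi, frame_period) {
  i0 <- ceiling(lo / frame_period - 1e-9)
  i1 <- floor(hi / frame_period + 1e-9) - 1
  if (i1 < i0) {
    stop_glomsep("window [%s, %s) s contains no complete frame at frame period %s s",
                 format(lo), format(hi), format(frame_period))
  }
  as.integer(seq(i0, i1))
}
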