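# Head-movement speed from 3-D tracking.

#' Instantaneous head speed from a 3-D trajectory
#'
#' Euclidean frame-to-frame displacement times the frame rate, then
#' moving-average smoothed (partial windows at the edges, so the output
#' keeps the `n_frames - 1` length contract). The default 12-frame window
#' at 120 frames/s smooths over 100 ms, matching the ~10 ms granularity of
#' infrared tracking.
#'
#' @param traj A [generate_head_trajectory()] result, or any tibble with
#'   uniform `time` and `x`, `y`, `z` columns (mm).
#' @param smoothing_window_frames Moving-average width in frames
#'   (1 = no smoothing).
#' @return A tibble with `time` (interval midpoints, s) and `speed`
#'   (mm/s), of length `n_frames - 1`.
#' @export
head_speed <- function(traj, smoothing_window_frames = 12) {
  if (!all(c("time", "x", "y", "z") %in% names(traj)))
    abort("`traj` needs `time`, `x`, `y`, `z` columns", class = "phasestim_data_error")
  n <- nrow(traj)
  if (n < 2) abort("need at least two frames", class = "phasestim_data_error")
  dt <- diff(traj$time)
  # tolerate microsecond-precision round-trips of non-terminating frame steps
  if (any(abs(dt - mean(dt)) > pmax(2e-6, 1e-6 * mean(dt))))
    abort("timestamps must be uniformly spaced", class = "phasestim_data_error")
  if (any(!is.finite(as.matrix(traj[, c("x", "y", "z")]))))
    abort("positions must be finite", class = "phasestim_data_error")
  disp <- sqrt(diff(traj$x)^2 + diff(traj$y)^2 + diff(traj$z)^2)
  speed <- disp / mean(dt)
  w <- max(1L, as.integer(smoothing_window_frames))
  if (w > 1) {
    # centered moving average with partial windows at the edges
    cs <- cumsum(c(0, speed))
    m <- length(speed)
    half <- w %/% 2
    lo <- pmax(seq_len(m) - half, 1L)
    hi <- pmin(seq_len(m) + (w - half - 1L), m)
    speed <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  tibble(time = traj$time[-n] + dt[1] / 2, speed = speed)
}

#' Mean speed per condition epoch
#'
#' Convenience aggregation of [head_speed()] over an [epoch_set()]: one
#' row per epoch with its mean speed, the unit fed into condition
#' contrasts such as [compare_epochs()].
#'
#' @param traj A head trajectory (see [head_speed()]).
#' @param epochs An [epoch_set()].
#' @param smoothing_window_frames Passed to [head_speed()].
#' @return A tibble with `condition`, `block`, `start`, `end`,
#'   `mean_speed` (mm/s).
#' @export
epoch_speeds <- function(traj, epochs, smoothing_window_frames = 12) {
  stopifnot(inherits(epochs, "epoch_set"))
  sp <- head_speed(traj, smoothing_window_frames)
  purrr::pmap_dfr(epochs, function(start, end, condition, block) {
    keep <- sp$time >= start & sp$time < end
    tibble(condition = condition, block = block, start = start, end = end,
           mean_speed = mean(sp$speed[keep]))
  })
}
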