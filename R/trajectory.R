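#' Construct a trajectory time series
#'
#' A `trajectory_series` is the package's core container: the time-stamped XY
#' path of one tracked point, sampled at a constant frame rate, with its
#' spatial units (`"mm"` or `"px"`) and optional pixel-to-mm calibration
#' attached. Coordinates follow the screen convention: origin at the
#' upper-left corner, x rightward, y downward.
#'
#' @param x,y numeric coordinate vectors of equal length (>= 2).
#' @param fps frame rate in frames per second.
#' @param units `"mm"` or `"px"`.
#' @param mm_per_px pixel-to-mm scale; `NA` when coordinates are already mm.
#' @param interpolated logical per-sample flag marking positions that were
#'   filled in (e.g. lost tracking frames).
#' @param start_time time of the first sample in seconds.
#' @return a data frame of class `trajectory_series` with columns `frame`,
#'   `time`, `x`, `y`, `interpolated` and attributes `fps`, `units`,
#'   `mm_per_px`.
#' @export
trajectory_series <- function(x, y, fps, units = c("mm", "px"),
                              mm_per_px = NA_real_,
                              interpolated = NULL, start_time = 0) {
  units <- match.arg(units)
  n <- length(x)
  check_that(n >= 2L && length(y) == n,
             "trajectory needs >= 2 samples with equal-length x and y")
  check_that(all(is.finite(x)) && all(is.finite(y)),
             "trajectory coordinates must be finite")
  check_scalar(fps, "fps", min = 0, strict_min = TRUE)
  interpolated <- interpolated %||% rep(FALSE, n)
  check_that(is.logical(interpolated) && length(interpolated) == n,
             "'interpolated' must be a logical vector matching the samples")
  frame <- seq_len(n) - 1L
  out <- data.frame(frame = frame,
                    time = start_time + frame / fps,
                    x = as.numeric(x), y = as.numeric(y),
                    interpolated = interpolated)
  attr(out, "fps") <- fps
  attr(out, "units") <- units
  attr(out, "mm_per_px") <- mm_per_px
  class(out) <- c("trajectory_series", "data.frame")
  out
}

traj_fps <- function(traj) attr(traj, "fps")
traj_units <- function(traj) attr(traj, "units")
traj_duration <- function(traj) (nrow(traj) - 1L) / traj_fps(traj)

# Subset a trajectory by row indices, preserving class and calibration.
traj_subset <- function(traj, idx) {
  out <- trajectory_series(traj$x[idx], traj$y[idx], traj_fps(traj),
                           units = traj_units(traj),
                           mm_per_px = attr(traj, "mm_per_px"),
                           interpolated = traj$interpolated[idx],
                           start_time = traj$time[idx[1L]])
  out$frame <- traj$frame[idx]
  out
}

#' Convert a pixel trajectory to millimetres
#'
#' @param traj a [trajectory_series()].
#' @param mm_per_px calibration from [calibrate_scale()]; defaults to the
#'   scale stored on the trajectory.
#' @return the trajectory in mm units.
#' @export
as_mm <- function(traj, mm_per_px = NULL) {
  stopifnot(inherits(traj, "trajectory_series"))
  if (traj_units(traj) == "mm") return(traj)
  scale <- mm_per_px %||% attr(traj, "mm_per_px")
  check_that(is.numeric(scale) && length(scale) == 1L && is.finite(scale) &&
               scale > 0,
             "cannot convert to mm: trajectory is uncalibrated (no mm_per_px)")
  out <- trajectory_series(traj$x * scale, traj$y * scale, traj_fps(traj),
                           units = "mm", mm_per_px = scale,
                           interpolated = traj$interpolated,
                           start_time = traj$time[1L])
  out$frame <- traj$frame
  out
}

#' @export
print.trajectory_series <- function(x, ...) {
  cat(sprintf("<trajectory_series> %d samples, %.4g s at %g fps [%s]\n",
              nrow(x), traj_duration(x), traj_fps(x), traj_units(x)))
  cat(sprintf("  x range [%.3g, %.3g], y range [%.3g, %.3g], %d interpolated\n",
              min(x$x), max(x$x), min(x$y), max(x$y), sum(x$interpolated)))
  invisible(x)
}

#' @export
plot.trajectory_series <- function(x, which = c("path", "time"), ...) {
  which <- match.arg(which)
  u <- traj_units(x)
  if (which == "path") {
    plot(x$x, x$y, type = "l", xlab = paste0("x [", u, "]"),
         ylab = paste0("y [", u, "]"), ...)
  } else {
    plot(x$time, x$x, type = "l", xlab = "time [s]",
         ylab = paste0("coordinate [", u, "]"), ...)
    lines(x$time, x$y, col = 2)
  }
  invisible(x)
}

#' Write / read a trajectory as CSV
#'
#' The on-disk layout has columns `frame,time_s,x,y,units,interpolated`; the
#' frame rate is recovered from the time column on read.
#'
#' @param traj a [trajectory_series()].
#' @param path file path.
#' @rdname trajectory_csv
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_series"))
  df <- data.frame(frame = traj$frame, time_s = traj$time,
                   x = traj$x, y = traj$y,
                   units = traj_units(traj),
                   interpolated = traj$interpolated)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @param mm_per_px optional calibration to attach on read.
#' @rdname trajectory_csv
#' @export
read_trajectory_csv <- function(path, mm_per_px = NA_real_) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time_s", "x", "y")
  check_that(all(need %in% names(df)),
             "trajectory CSV must have columns frame,time_s,x,y")
  dt <- diff(df$time_s)
  check_that(all(abs(dt - dt[1L]) < 1e-6 * dt[1L]),
             "trajectory CSV must be sampled at a constant rate")
  units <- if ("units" %in% names(df)) as.character(df$units[1L]) else "mm"
  interp <- if ("interpolated" %in% names(df)) as.logical(df$interpolated)
            else NULL
  trajectory_series(df$x, df$y, fps = 1 / dt[1L], units = units,
                    mm_per_px = mm_per_px, interpolated = interp,
                    start_time = df$time_s[1L])
}
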