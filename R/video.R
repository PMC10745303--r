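#' Render trajectories as a synthetic marker video
#'
#' Draws each trajectory as a high-contrast anti-aliased disc moving over a
#' static textured background, one frame per trajectory sample, emulating a
#' high-definition tremor recording (default 1280 x 720 px at the
#' trajectories' frame rate). The background texture is fixed by `seed` so
#' rendered videos are bit-reproducible. Frames are grayscale matrices in
#' `[0, 1]` with `frame[row, col]` = (y, x) and pixel centres at integer
#' coordinates, origin at the upper-left corner.
#'
#' Frames are synthesised lazily: the returned `marker_video` object holds a
#' frame closure rather than the full stack, so hour-long 720p videos fit in
#' memory. Use [get_frame()] or [as.array()] to materialise frames.
#'
#' @param trajectories a [trajectory_series()] (mm units) or list of them,
#'   all with the same length and fps.
#' @param frame_size `c(width, height)` in px.
#' @param marker_radius disc radius in px.
#' @param mm_per_px spatial scale of the simulated camera.
#' @param origins_px optional list of `c(x, y)` px positions mapped to each
#'   trajectory's (0, 0) mm; defaults to the frame centre (single
#'   trajectory) or positions spread along the horizontal midline.
#' @param seed RNG seed fixing the background texture.
#' @return an object of class `marker_video` with elements `n_frames`,
#'   `width`, `height`, `fps`, `positions_px` (list of n x 2 matrices of
#'   ground-truth marker centres) and a frame accessor.
#' @export
render_marker_video <- function(trajectories, frame_size = c(1280, 720),
                                marker_radius = 8, mm_per_px = 0.5,
                                origins_px = NULL, seed = 1L) {
  if (inherits(trajectories, "trajectory_series")) {
    trajectories <- list(trajectories)
  }
  check_that(length(trajectories) >= 1L &&
               all(vapply(trajectories, inherits, TRUE, "trajectory_series")),
             "'trajectories' must be trajectory_series objects")
  n <- nrow(trajectories[[1L]])
  fps <- traj_fps(trajectories[[1L]])
  for (tr in trajectories) {
    check_that(nrow(tr) == n && traj_fps(tr) == fps,
               "all trajectories must share length and fps")
    check_that(traj_units(tr) == "mm", "trajectories must be in mm units")
  }
  W <- as.integer(frame_size[1L]); H <- as.integer(frame_size[2L])
  check_that(W >= 16L && H >= 16L, "frame_size too small")
  check_scalar(marker_radius, "marker_radius", min = 1)
  check_scalar(mm_per_px, "mm_per_px", min = 0, strict_min = TRUE)

  k <- length(trajectories)
  if (is.null(origins_px)) {
    origins_px <- if (k == 1L) list(c(W / 2, H / 2)) else
      lapply(seq_len(k), function(i) c(W * i / (k + 1), H / 2))
  }
  check_that(length(origins_px) == k, "need one origin per trajectory")

  positions_px <- vector("list", k)
  margin <- marker_radius + 2
  for (i in seq_len(k)) {
    px <- origins_px[[i]][1L] + trajectories[[i]]$x / mm_per_px
    py <- origins_px[[i]][2L] + trajectories[[i]]$y / mm_per_px
    bad <- which(px < margin | px > W + 1 - margin |
                   py < margin | py > H + 1 - margin)
    if (length(bad)) {
      stop(sprintf("marker %d leaves the frame at frame %d (of %d)",
                   i, bad[1L], n), call. = FALSE)
    }
    positions_px[[i]] <- cbind(x = px, y = py)
  }

  background <- with_seed(seed, {
    gh <- max(4L, ceiling(H / 32)); gw <- max(4L, ceiling(W / 32))
    coarse <- matrix(runif(gh * gw, 0.25, 0.5), gh, gw)
    smooth <- interp_matrix(H, gh) %*% coarse %*% t(interp_matrix(W, gw))
    grain <- matrix(runif(H * W, -0.02, 0.02), H, W)
    matrix(pmax(0, pmin(1, smooth + grain)), H, W)
  })

  frame_fn <- function(i) {
    fr <- background
    for (j in seq_len(k)) {
      fr <- draw_disc(fr, positions_px[[j]][i, 1L], positions_px[[j]][i, 2L],
                      marker_radius, intensity = 1)
    }
    fr
  }

  structure(list(frame_fn = frame_fn, n_frames = n, width = W, height = H,
                 fps = fps, marker_radius = marker_radius,
                 mm_per_px = mm_per_px, positions_px = positions_px,
                 background = background),
            class = "marker_video")
}

# Composite an anti-aliased disc (1 px linear edge ramp) onto frame matrix.
draw_disc <- function(frame, xc, yc, radius, intensity = 1) {
  H <- nrow(frame); W <- ncol(frame)
  r0 <- max(1L, floor(yc - radius - 2)); r1 <- min(H, ceiling(yc + radius + 2))
  c0 <- max(1L, floor(xc - radius - 2)); c1 <- min(W, ceiling(xc + radius + 2))
  rows <- r0:r1; cols <- c0:c1
  d <- sqrt(outer((rows - yc)^2, (cols - xc)^2, `+`))
  a <- pmax(0, pmin(1, radius + 0.5 - d))
  frame[rows, cols] <- frame[rows, cols] * (1 - a) + intensity * a
  frame
}

#' Extract one frame of a video
#'
#' @param video a `marker_video`, a `height x width x n` array, or a list of
#'   frame matrices.
#' @param i frame index (1-based).
#' @return a grayscale matrix.
#' @export
get_frame <- function(video, i) {
  if (inherits(video, "marker_video")) return(video$frame_fn(i))
  if (is.array(video) && length(dim(video)) == 3L) return(video[, , i])
  if (is.list(video)) return(video[[i]])
  stop("unsupported video representation", call. = FALSE)
}

n_frames <- function(video) {
  if (inherits(video, "marker_video")) return(video$n_frames)
  if (is.array(video) && length(dim(video)) == 3L) return(dim(video)[3L])
  if (is.list(video)) return(length(video))
  stop("unsupported video representation", call. = FALSE)
}

video_fps <- function(video, fps = NULL) {
  if (!is.null(fps)) return(fps)
  if (inherits(video, "marker_video")) return(video$fps)
  attr(video, "fps") %||% 25
}

#' @export
print.marker_video <- function(x, ...) {
  cat(sprintf("<marker_video> %d frames %dx%d px @ %g fps, %d marker(s)\n",
              x$n_frames, x$width, x$height, x$fps, length(x$positions_px)))
  invisible(x)
}

#' @export
as.array.marker_video <- function(x, ...) {
  out <- array(0, dim = c(x$height, x$width, x$n_frames))
  for (i in seq_len(x$n_frames)) out[, , i] <- x$frame_fn(i)
  attr(out, "fps") <- x$fps
  out
}

#' Write / read a video as a numbered PNG sequence
#'
#' @param video anything accepted by [get_frame()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix; frames are written as
#'   `<prefix>_00001.png` etc.
#' @return `write_png_sequence` returns the file paths;
#'   `read_png_sequence` returns a lazy video object usable with
#'   [track_point()].
#' @rdname png_sequence
#' @export
write_png_sequence <- function(video, dir, prefix = "frame") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nf <- n_frames(video)
  paths <- file.path(dir, sprintf("%s_%05d.png", prefix, seq_len(nf)))
  for (i in seq_len(nf)) {
    png::writePNG(get_frame(video, i), paths[i])
  }
  invisible(paths)
}

#' @param paths PNG file paths in frame order, or a directory containing
#'   them.
#' @param fps frame rate to attach.
#' @rdname png_sequence
#' @export
read_png_sequence <- function(paths, fps = 25) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.png$", full.names = TRUE))
  }
  check_that(length(paths) >= 1L, "no PNG frames found")
  read1 <- function(p) {
    im <- png::readPNG(p)
    if (length(dim(im)) == 3L) im <- (im[, , 1L] + im[, , 2L] + im[, , 3L]) / 3
    im
  }
  f1 <- read1(paths[1L])
  structure(list(frame_fn = function(i) read1(paths[i]),
                 n_frames = length(paths),
                 width = ncol(f1), height = nrow(f1), fps = fps,
                 marker_radius = NA_real_, mm_per_px = NA_real_,
                 positions_px = NULL, background = NULL),
            class = "marker_video")
}
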