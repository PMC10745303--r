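#' Define a region of interest to track
#'
#' The template window is cut from the first frame around `center`; during
#' tracking each subsequent frame is searched within `search_radius` px of
#' the previous position. `search_radius` must exceed the expected per-frame
#' motion of the point (for tremor: peak velocity in px/s divided by fps).
#'
#' @param center `c(x, y)` position in the first frame, px.
#' @param label one of `"finger"`, `"wrist"`, `"elbow"`, `"pen_tip"`,
#'   `"custom"`.
#' @param template_half_size half-width of the square template, px (the
#'   template is `(2 * template_half_size + 1)^2`).
#' @param search_radius search half-width around the previous position, px.
#' @return an object of class `roi_selection`.
#' @export
roi_selection <- function(center, label = c("custom", "finger", "wrist",
                                            "elbow", "pen_tip"),
                          template_half_size = 12, search_radius = 30) {
  label <- match.arg(label)
  check_that(is.numeric(center) && length(center) == 2L &&
               all(is.finite(center)), "invalid 'center': need c(x, y)")
  check_scalar(template_half_size, "template_half_size", min = 2)
  check_scalar(search_radius, "search_radius", min = 1)
  structure(list(label = label, center = as.numeric(center),
                 template_half_size = as.integer(template_half_size),
                 search_radius = as.integer(search_radius)),
            class = "roi_selection")
}

#' Track a point through a video by template matching
#'
#' For every frame the template (cut from frame 1 around the ROI centre) is
#' matched by zero-normalized cross-correlation within a search window
#' centred on the previous position; the correlation peak is refined to
#' sub-pixel accuracy by separable quadratic interpolation. Frames whose
#' best score falls below `score_threshold` are flagged lost and their
#' positions filled by linear interpolation from neighbouring good frames
#' (the flag is preserved on the trajectory). Tracking aborts with an error
#' when more than `max_lost_fraction` of frames are lost.
#'
#' Because the correlation is zero-normalized the recovered trajectory is
#' invariant to global intensity offset or gain changes of the video.
#'
#' @param video a `marker_video` from [render_marker_video()] /
#'   [read_png_sequence()], a `height x width x n` array, or list of frames.
#' @param roi a [roi_selection()].
#' @param score_threshold minimum acceptable correlation score in `[-1, 1]`.
#' @param max_lost_fraction maximum tolerated fraction of lost frames.
#' @param template_update exponential template-update rate in `[0, 1]`:
#'   0 (default) keeps the frame-1 template fixed; small positive values
#'   blend in the matched patch each frame.
#' @param mm_per_px optional calibration; when given the returned
#'   trajectory is in mm.
#' @param fps frame rate override for raw array/list videos.
#' @return an object of class `tracking_result`: list with `trajectory`
#'   (a [trajectory_series()]), per-frame `scores`, and `lost_frames`
#'   (indices).
#' @export
track_point <- function(video, roi, score_threshold = 0.5,
                        max_lost_fraction = 0.2, template_update = 0,
                        mm_per_px = NULL, fps = NULL) {
  stopifnot(inherits(roi, "roi_selection"))
  check_scalar(score_threshold, "score_threshold", min = -1, max = 1)
  check_scalar(max_lost_fraction, "max_lost_fraction", min = 0, max = 1)
  check_scalar(template_update, "template_update", min = 0, max = 1)
  nf <- n_frames(video)
  check_that(nf >= 2L, "need at least 2 frames to track")
  fps <- video_fps(video, fps)

  f1 <- get_frame(video, 1L)
  H <- nrow(f1); W <- ncol(f1)
  h <- roi$template_half_size
  cx <- round(roi$center[1L]); cy <- round(roi$center[2L])
  check_that(cx - h >= 1 && cx + h <= W && cy - h >= 1 && cy + h <= H,
             "ROI template window falls outside the first frame")
  template <- f1[(cy - h):(cy + h), (cx - h):(cx + h)]
  sr <- roi$search_radius

  pos <- matrix(NA_real_, nf, 2L)
  scores <- numeric(nf)
  prev <- roi$center
  for (i in seq_len(nf)) {
    fr <- if (i == 1L) f1 else get_frame(video, i)
    icx <- round(prev[1L]); icy <- round(prev[2L])
    r0 <- max(1L, icy - sr - h); r1 <- min(H, icy + sr + h)
    c0 <- max(1L, icx - sr - h); c1 <- min(W, icx + sr + h)
    sc <- ncc_search(fr[r0:r1, c0:c1, drop = FALSE], template)
    best <- arrayInd(which.max(sc), dim(sc))
    bi <- best[1L]; bj <- best[2L]
    scores[i] <- sc[bi, bj]
    if (scores[i] >= score_threshold) {
      off <- c(subpixel_offset(sc, bi, bj, "col"),
               subpixel_offset(sc, bi, bj, "row"))
      px <- c0 + h + (bj - 1L) + off[1L]
      py <- r0 + h + (bi - 1L) + off[2L]
      pos[i, ] <- c(px, py)
      prev <- c(px, py)
      if (template_update > 0) {
        pcx <- round(px); pcy <- round(py)
        if (pcx - h >= 1 && pcx + h <= W && pcy - h >= 1 && pcy + h <= H) {
          patch <- fr[(pcy - h):(pcy + h), (pcx - h):(pcx + h)]
          template <- (1 - template_update) * template +
            template_update * patch
        }
      }
    }
  }

  lost <- which(is.na(pos[, 1L]))
  if (length(lost) > max_lost_fraction * nf) {
    stop(sprintf(
      "tracking failure: %d of %d frames (%.1f%%) below score threshold %.2f",
      length(lost), nf, 100 * length(lost) / nf, score_threshold),
      call. = FALSE)
  }
  if (length(lost)) {
    check_that(length(lost) < nf - 1L, "tracking failure: no usable frames")
    good <- setdiff(seq_len(nf), lost)
    pos[lost, 1L] <- approx(good, pos[good, 1L], xout = lost, rule = 2)$y
    pos[lost, 2L] <- approx(good, pos[good, 2L], xout = lost, rule = 2)$y
  }

  interp <- rep(FALSE, nf); interp[lost] <- TRUE
  traj <- trajectory_series(pos[, 1L], pos[, 2L], fps, units = "px",
                            mm_per_px = mm_per_px %||% NA_real_,
                            interpolated = interp)
  if (!is.null(mm_per_px)) traj <- as_mm(traj, mm_per_px)
  structure(list(trajectory = traj, scores = scores, lost_frames = lost,
                 roi = roi, score_threshold = score_threshold,
                 template_update = template_update),
            class = "tracking_result")
}

# Quadratic (three-point parabola) refinement of the correlation peak along
# one axis; returns an offset in (-0.5, 0.5), or 0 at matrix borders or for
# non-concave neighbourhoods.
subpixel_offset <- function(sc, bi, bj, axis = c("row", "col")) {
  axis <- match.arg(axis)
  if (axis == "row") {
    if (bi <= 1L || bi >= nrow(sc)) return(0)
    sm1 <- sc[bi - 1L, bj]; s0 <- sc[bi, bj]; sp1 <- sc[bi + 1L, bj]
  } else {
    if (bj <= 1L || bj >= ncol(sc)) return(0)
    sm1 <- sc[bi, bj - 1L]; s0 <- sc[bi, bj]; sp1 <- sc[bi, bj + 1L]
  }
  den <- sm1 - 2 * s0 + sp1
  if (den >= 0) return(0)
  off <- 0.5 * (sm1 - sp1) / den
  max(-0.5, min(0.5, off))
}

#' @export
print.tracking_result <- function(x, ...) {
  cat(sprintf(
    "<tracking_result> %d frames, %d lost (%.1f%%), median score %.3f\n",
    nrow(x$trajectory), length(x$lost_frames),
    100 * length(x$lost_frames) / nrow(x$trajectory), median(x$scores)))
  invisible(x)
}

#' Pixel-to-mm calibration from a reference length
#'
#' The recordings carry no intrinsic scale; calibration uses an object of
#' known physical length visible in the frame (typically the 15 cm line of
#' the drawing task itself).
#'
#' @param reference_length_mm known physical length, mm.
#' @param p1,p2 the endpoints of that length in the image, `c(x, y)` px.
#' @return the scale in mm per px.
#' @examples
#' calibrate_scale(150, c(0, 0), c(300, 0))   # 0.5 mm/px
#' @export
calibrate_scale <- function(reference_length_mm, p1, p2) {
  check_scalar(reference_length_mm, "reference_length_mm", min = 0,
               strict_min = TRUE)
  check_that(is.numeric(p1) && length(p1) == 2L &&
               is.numeric(p2) && length(p2) == 2L,
             "endpoints must be c(x, y) pixel coordinates")
  d <- sqrt(sum((p2 - p1)^2))
  check_that(d > 0, "calibration endpoints coincide")
  reference_length_mm / d
}
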