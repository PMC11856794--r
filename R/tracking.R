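# Sub-pixel tip tracking by normalized cross-correlation against a
# reference patch from the first frame, searched along one axis, with
# parabolic refinement of the correlation peak.  The gel pulls the probe
# tip along a single direction, so 1-D tracking suffices; the reference
# is fixed (not rolling) to avoid drift accumulation on periodic motion.

#' Track the probe tip through an image stack
#'
#' @param frames A height x width x n array in [0, 1], or a
#'   \code{\link{render_frames}} result.
#' @param axis Motion axis: \code{"y"} (rows, default) or \code{"x"}
#'   (columns).
#' @param template_cfg List of options: \code{center} (row, col of the
#'   template centre; default the darkest pixel of frame 1),
#'   \code{half_size} (template half-extent in px, default 15),
#'   \code{search} (maximum shift searched in px, default 20),
#'   \code{min_confidence} (NCC below which a frame is flagged,
#'   default 0.5), \code{var_floor} (minimum template variance,
#'   default 1e-6).
#' @return A list of class \code{"tracking_result"}: \code{position_px}
#'   (per-frame tip position along the axis, sub-pixel, frame-1 referenced),
#'   \code{confidence} (max NCC in [0,1] per frame), \code{flagged}
#'   (logical, low-confidence frames), \code{axis}.
#' @export
track_tip <- function(frames, axis = c("y", "x"), template_cfg = list()) {
  axis <- match.arg(axis)
  if (inherits(frames, "frame_stack")) frames <- frames$frames
  if (length(dim(frames)) != 3L)
    stop("'frames' must be a height x width x n array", call. = FALSE)
  n <- dim(frames)[3]
  if (n < 2L) stop("need at least 2 frames", call. = FALSE)
  if (axis == "x") frames <- aperm(frames, c(2, 1, 3))
  H <- dim(frames)[1]; W <- dim(frames)[2]

  cfg <- utils::modifyList(list(center = NULL, half_size = 10L,
                                search = 20L, min_confidence = 0.5,
                                var_floor = 1e-6), template_cfg)
  if (is.null(cfg$center)) {
    # centre the template where the image actually moves: the pixel with
    # maximal temporal variance (falling back to the darkest pixel of
    # frame 1 for static stacks)
    mu <- rowMeans(frames, dims = 2L)
    v <- rowMeans(frames^2, dims = 2L) - mu^2
    i0 <- if (max(v) > 1e-12) which.max(v) else which.min(frames[, , 1L])
    cfg$center <- c((i0 - 1L) %% H + 1L, (i0 - 1L) %/% H + 1L)
  }
  hs <- cfg$half_size
  r0 <- round(cfg$center[1]); c0 <- round(cfg$center[2])
  rr <- max(1L, r0 - hs):min(H, r0 + hs)
  ccs <- max(1L, c0 - hs):min(W, c0 + hs)
  tpl <- frames[rr, ccs, 1L]
  tv <- as.numeric(tpl) - mean(tpl)
  if (mean(tv^2) < cfg$var_floor)
    stop("reference patch is featureless (variance below floor)",
         call. = FALSE)

  shifts <- -cfg$search:cfg$search
  ok_shift <- vapply(shifts, function(s)
    min(rr) + s >= 1L && max(rr) + s <= H, logical(1))
  shifts <- shifts[ok_shift]
  if (length(shifts) < 3L)
    stop("search range does not fit in the frame", call. = FALSE)

  pos <- numeric(n); conf <- numeric(n)
  for (f in seq_len(n)) {
    fr <- frames[, , f]
    cc <- vapply(shifts, function(s) {
      patch <- fr[rr + s, ccs]
      pv <- as.numeric(patch) - mean(patch)
      denom <- sqrt(sum(tv^2) * sum(pv^2))
      if (denom == 0) 0 else sum(tv * pv) / denom
    }, numeric(1))
    ib <- which.max(cc)
    delta <- 0
    if (ib > 1L && ib < length(shifts)) {
      den <- cc[ib - 1L] - 2 * cc[ib] + cc[ib + 1L]
      if (den < 0) delta <- 0.5 * (cc[ib - 1L] - cc[ib + 1L]) / den
      if (abs(delta) > 1) delta <- 0
    }
    pos[f] <- shifts[ib] + delta
    conf[f] <- max(0, min(1, cc[ib]))
  }
  structure(list(position_px = pos, confidence = conf,
                 flagged = conf < cfg$min_confidence, axis = axis),
            class = "tracking_result")
}

#' Convert a tracking result to a displacement trace
#'
#' Low-confidence frames are replaced by linear interpolation from their
#' neighbours, with a warning.
#'
#' @param result A \code{\link{track_tip}} result.
#' @param fps Frame rate in Hz (default 60).
#' @param pixel_scale Metres per pixel.
#' @return A \code{\link{displacement_trace}} (displacement relative to
#'   the first frame).
#' @export
tracking_to_trace <- function(result, fps = 60, pixel_scale) {
  stopifnot(inherits(result, "tracking_result"))
  if (missing(pixel_scale) || pixel_scale <= 0)
    stop("'pixel_scale' (m/px) is required", call. = FALSE)
  pos <- result$position_px
  n <- length(pos)
  if (any(result$flagged)) {
    warning(sum(result$flagged),
            " low-confidence frame(s) excluded and interpolated",
            call. = FALSE)
    good <- which(!result$flagged)
    if (length(good) < 2L)
      stop("too few confident frames to build a trace", call. = FALSE)
    pos <- stats::approx(good, pos[good], xout = seq_len(n), rule = 2)$y
  }
  displacement_trace((seq_len(n) - 1L) / fps, pos * pixel_scale,
                     pixel_scale = pixel_scale)
}
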