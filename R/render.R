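# Synthetic video rendering: a dark horizontal wire on a bright background
# whose tip row follows the displacement trace.  Stands in for the
# microscope recordings of the real instrument; used to validate the
# tracking module against known sub-pixel ground truth.

#' Rendering configuration for synthetic probe video
#'
#' @param width,height Frame size in pixels.
#' @param pixel_scale Metres per pixel.
#' @param wire_sigma_px Gaussian half-width of the wire's intensity
#'   profile in pixels (anti-aliased rendering, default 1.5).
#' @param wire_depth Intensity drop of the wire below background, in
#'   [0, 1] (default 0.7).
#' @param background Background intensity in [0, 1] (default 0.9).
#' @param tip_col Column of the wire tip (default: 20 px from the right
#'   edge); the wire spans columns 1..tip_col.
#' @param base_row Resting row of the wire (default: frame centre).
#' @param hook_offset_px,hook_sigma_px Position (columns past the tip) and
#'   Gaussian radius of the dark hook marker at the free end; the hook
#'   follows the tip displacement rigidly and is the natural tracking
#'   target (set \code{hook_sigma_px = 0} to disable).
#' @return A list of class \code{"render_config"}.
#' @export
render_config <- function(width = 120L, height = 80L, pixel_scale = 1e-6,
                          wire_sigma_px = 1.5, wire_depth = 0.7,
                          background = 0.9, tip_col = NULL, base_row = NULL,
                          hook_offset_px = 6, hook_sigma_px = 3) {
  if (is.null(tip_col)) tip_col <- width - 20L
  if (is.null(base_row)) base_row <- height / 2
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_scale = pixel_scale, wire_sigma_px = wire_sigma_px,
                 wire_depth = wire_depth, background = background,
                 tip_col = as.integer(tip_col), base_row = base_row,
                 hook_offset_px = hook_offset_px,
                 hook_sigma_px = hook_sigma_px),
            class = "render_config")
}

#' Render a displacement trace as an 8-bit grayscale image stack
#'
#' Each frame shows a dark wire along the x (column) axis whose row
#' position at the tip follows the trace; motion is along the y (row)
#' axis. Intensities are quantized to 8 bits. The true sub-pixel tip rows
#' are returned alongside as tracking ground truth.
#'
#' @param trace A \code{\link{displacement_trace}} (values in metres;
#'   converted to pixels via the config's \code{pixel_scale}).
#' @param cfg A \code{\link{render_config}}.
#' @return A list of class \code{"frame_stack"}: \code{frames} (array
#'   height x width x n, values in [0,1] on the 8-bit grid),
#'   \code{truth_px} (tip row per frame, sub-pixel), \code{fps},
#'   \code{pixel_scale}.
#' @export
render_frames <- function(trace, cfg = render_config()) {
  stopifnot(inherits(trace, "displacement_trace"),
            inherits(cfg, "render_config"))
  disp_px <- trace$values / cfg$pixel_scale
  rows <- cfg$base_row + disp_px
  margin <- 3 * cfg$wire_sigma_px
  if (any(rows < 1 + margin) || any(rows > cfg$height - margin))
    stop("wire tip leaves the frame: enlarge the frame or reduce motion",
         call. = FALSE)
  n <- length(rows)
  frames <- array(cfg$background, dim = c(cfg$height, cfg$width, n))
  yy <- seq_len(cfg$height)
  xx <- seq_len(cfg$width)
  hook_col <- cfg$tip_col + cfg$hook_offset_px
  for (f in seq_len(n)) {
    # straight wire: clamped end held at base_row, tip at rows[f]
    for (cc in seq_len(cfg$tip_col)) {
      wr <- cfg$base_row + (rows[f] - cfg$base_row) * (cc - 1) /
        (cfg$tip_col - 1)
      prof <- cfg$wire_depth * exp(-(yy - wr)^2 / (2 * cfg$wire_sigma_px^2))
      frames[, cc, f] <- frames[, cc, f] - prof
    }
    if (cfg$hook_sigma_px > 0) {
      # rigid hook marker riding on the tip
      blob <- cfg$wire_depth *
        exp(-outer((yy - rows[f])^2, (xx - hook_col)^2, "+") /
              (2 * cfg$hook_sigma_px^2))
      frames[, , f] <- frames[, , f] - blob
    }
  }
  frames[frames < 0] <- 0
  frames <- round(frames * 255) / 255        # 8-bit quantization
  structure(list(frames = frames, truth_px = rows, fps = trace$fs,
                 pixel_scale = cfg$pixel_scale),
            class = "frame_stack")
}

#' Write / read a frame stack as multi-page 8-bit grayscale TIFF
#'
#' @param stack A \code{\link{render_frames}} result (or any
#'   height x width x n array in [0,1]).
#' @param path TIFF file path.
#' @return \code{write_frames} returns \code{path} invisibly;
#'   \code{read_frames} returns a height x width x n array.
#' @export
write_frames <- function(stack, path) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  pages <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    arr[, , i] <- p
  }
  arr
}
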