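# Parametric color rendering: 255 gradation levels to a blue -> green ->
# yellow -> red palette, composed over the grayscale frame.

# Palette anchors (level -> RGB). Only the semantic direction is fixed by the
# method (blue = stable tissue, yellow-red = strong fluctuation); the anchor
# values are this package's documented, deterministic choice.
fluct_anchors <- function() {
  list(levels = c(0L, 85L, 170L, 255L),
       rgb = rbind(c(0, 0, 255),      # blue
                   c(0, 255, 128),    # cyan-green
                   c(255, 255, 0),    # yellow
                   c(255, 0, 0)))     # red
}

#' Map 0-255 fluctuation levels to gradation colors
#'
#' Linear interpolation between fixed anchors: level 0 is blue (0,0,255), 85
#' is cyan-green (0,255,128), 170 is yellow (255,255,0) and 255 is red
#' (255,0,0). The mapping is deterministic and bit-exact (channels are
#' interpolated linearly and rounded half-up).
#'
#' @param level integer matrix of levels in 0..255.
#' @param valid optional logical matrix; invalid pixels get color (0,0,0) and
#'   are excluded by [overlay_frame()]'s show mask.
#' @return Integer array rows x cols x 3 with values in 0..255.
#' @export
colorize <- function(level, valid = NULL) {
  lv <- level
  lv[is.na(lv)] <- 0L
  if (min(lv) < 0L || max(lv) > 255L) fi_stop("levels must be in 0..255")
  an <- fluct_anchors()
  out <- array(0L, c(dim(level), 3L))
  for (ch in 1:3) {
    out[, , ch] <- as.integer(round_half_up(
      stats::approx(an$levels, an$rgb[, ch], xout = as.numeric(lv))$y))
  }
  if (!is.null(valid)) {
    for (ch in 1:3) {
      pl <- out[, , ch]
      pl[!valid] <- 0L
      out[, , ch] <- pl
    }
  }
  out
}

#' Compose a color overlay on a grayscale frame
#'
#' On shown pixels the output is `alpha * color + (1 - alpha) * gray`
#' (channel-wise, rounded half-up); elsewhere the pure grayscale frame shows
#' through unchanged.
#'
#' @param frame numeric matrix in \eqn{[0,1]} (the background B-mode frame).
#' @param colors integer rows x cols x 3 array from [colorize()].
#' @param alpha overlay opacity in \eqn{[0,1]}.
#' @param show_mask logical matrix of pixels where color is displayed.
#' @return Integer rows x cols x 3 array in 0..255.
#' @export
overlay_frame <- function(frame, colors, alpha, show_mask) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    fi_stop("'alpha' must be in [0,1]")
  }
  if (!identical(dim(frame), dim(colors)[1:2]) ||
      !identical(dim(frame), dim(show_mask))) {
    fi_stop("frame, colors and show_mask shapes must match")
  }
  gray <- round_half_up(frame * 255)
  out <- array(0L, dim(colors))
  for (ch in 1:3) {
    mixed <- round_half_up(alpha * colors[, , ch] + (1 - alpha) * gray)
    plane <- gray
    plane[show_mask] <- mixed[show_mask]
    out[, , ch] <- as.integer(plane)
  }
  out
}

#' Render the overlay of a fitted fluctuation map
#'
#' Colors are shown only where the map is valid and the level reaches
#' `display_min_level`, mimicking displays where quiet tissue shows no color.
#' This display threshold is independent of the detection threshold used by
#' [classify_lesion()].
#'
#' @param fmap a [fluctmap] object.
#' @param alpha overlay opacity (default 0.5).
#' @param display_min_level minimum level that is colored (default 64).
#' @return Integer rows x cols x 3 array in 0..255.
#' @export
render_overlay <- function(fmap, alpha = 0.5, display_min_level = 64L) {
  stopifnot(inherits(fmap, "fluctmap"))
  show <- fmap$valid & !is.na(fmap$level) & fmap$level >= display_min_level
  cols <- colorize(fmap$level, fmap$valid)
  overlay_frame(fmap$frame0, cols, alpha, show)
}

#' Plot a fluctuation map as a color overlay
#'
#' @param x a [fluctmap] object.
#' @param alpha,display_min_level see [render_overlay()].
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.fluctmap <- function(x, alpha = 0.5, display_min_level = 64L, ...) {
  rgb <- render_overlay(x, alpha = alpha, display_min_level = display_min_level)
  nr <- dim(rgb)[1L]; nc <- dim(rgb)[2L]
  ras <- grDevices::as.raster(rgb / 255)
  graphics::plot(c(0, nc), c(0, nr), type = "n", asp = 1, xlab = "col",
                 ylab = "row", ...)
  graphics::rasterImage(ras, 0, 0, nc, nr)
  invisible(x)
}
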