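#' Local cross-correlation between two consecutive frames
#'
#' At every analysis point the cross-correlation coefficient R is the Pearson
#' correlation of the two frames' intensities over the square window centred
#' there:
#' \deqn{R = \frac{\sum_i\sum_j (I_n(i,j)-\bar I_n)(I_{n-1}(i,j)-\bar I_{n-1})}
#'   {\sqrt{\sum_i\sum_j (I_n(i,j)-\bar I_n)^2}\,
#'    \sqrt{\sum_i\sum_j (I_{n-1}(i,j)-\bar I_{n-1})^2}}}
#' where the sums run over the window and \eqn{\bar I_n} is the window mean of
#' frame n. Stable speckle gives R near 1; decorrelating speckle drives R
#' toward 0. R is invariant under independent positive linear intensity
#' transforms of each frame.
#'
#' Windows are never padded: a pixel whose window leaves the frame is marked
#' invalid rather than computed from fabricated border values, as is a pixel
#' where either window has (numerically) zero variance. The implementation
#' uses integral-image box sums; it is algebraically identical to the naive
#' double sum.
#'
#' @param frame_prev,frame_curr numeric matrices of the same shape (frames
#'   n-1 and n).
#' @param window_radius_px window radius in pixels, scalar or (row, col);
#'   the full window is `(2*radius+1)` pixels wide per axis. Must be >= 1.
#' @param roi optional [roi_mask()]; analysis points outside it are invalid.
#' @param valid_prev,valid_curr optional logical matrices of per-pixel data
#'   validity (from motion compensation); a window containing any invalid
#'   pixel in either frame is invalid.
#' @return A list with `r` (numeric matrix, `NA` where invalid) and `valid`
#'   (logical matrix).
#' @export
local_xcorr_pair <- function(frame_prev, frame_curr, window_radius_px,
                             roi = NULL, valid_prev = NULL, valid_curr = NULL) {
  if (!identical(dim(frame_prev), dim(frame_curr))) {
    fi_stop("frames must have the same shape")
  }
  rad <- as_radius_pair(window_radius_px, 1L, "window_radius_px")
  nr <- nrow(frame_prev); nc <- ncol(frame_prev)
  N <- (2L * rad[1L] + 1L) * (2L * rad[2L] + 1L)

  sA <- box_sum(frame_prev, rad)
  sB <- box_sum(frame_curr, rad)
  sAA <- box_sum(frame_prev * frame_prev, rad)$sum
  sBB <- box_sum(frame_curr * frame_curr, rad)$sum
  sAB <- box_sum(frame_prev * frame_curr, rad)$sum

  covW <- sAB - sA$sum * sB$sum / N
  varA <- sAA - sA$sum^2 / N
  varB <- sBB - sB$sum^2 / N

  valid <- sA$support & varA > 1e-12 & varB > 1e-12
  if (!is.null(valid_prev)) {
    valid <- valid & box_sum(1 * !valid_prev, rad)$sum < 0.5
  }
  if (!is.null(valid_curr)) {
    valid <- valid & box_sum(1 * !valid_curr, rad)$sum < 0.5
  }
  if (!is.null(roi)) valid <- valid & roi$mask

  r <- matrix(NA_real_, nr, nc)
  r[valid] <- covW[valid] / sqrt(varA[valid] * varB[valid])
  list(r = r, valid = valid)
}

# R for every consecutive frame pair of a cine: arrays (T-1) x rows x cols.
rmap_consecutive <- function(cine, roi, window_radius_px) {
  T <- n_frames(cine)
  shp <- frame_shape(cine)
  r <- array(NA_real_, c(T - 1L, shp))
  valid <- array(FALSE, c(T - 1L, shp))
  for (t in 2:T) {
    vp <- if (is.null(cine$valid)) NULL else cine$valid[t - 1L, , ]
    vc <- if (is.null(cine$valid)) NULL else cine$valid[t, , ]
    sl <- local_xcorr_pair(cine$frames[t - 1L, , ], cine$frames[t, , ],
                           window_radius_px, roi = roi,
                           valid_prev = vp, valid_curr = vc)
    r[t - 1L, , ] <- sl$r
    valid[t - 1L, , ] <- sl$valid
  }
  list(r = r, valid = valid, window_radius_px = as_radius_pair(window_radius_px, 1L, "window_radius_px"))
}

#' Degree of coincidence from a stack of cross-correlation maps
#'
#' The degree of coincidence at a point p is the mean of `clamp(R, 0, 1)`
#' taken over every valid frame pair and every valid neighbour within the
#' square spatial neighbourhood of p. Negative R (anticorrelated speckle)
#' counts as zero coincidence, matching the 0-1 range that is mapped to the
#' 255 gradation colors. Points with no valid contributing samples are
#' invalid. The neighbourhood is clipped at the frame border (it is an
#' average over whatever valid samples exist, not a windowed convolution that
#' would require full support).
#'
#' @param rmap list with 3D arrays `r` and `valid` as returned by the
#'   consecutive-pair correlation stage.
#' @param neighborhood_radius_px spatial neighbourhood radius in pixels,
#'   scalar or (row, col); 0 means the point itself only.
#' @return A list with `coincidence` (matrix in \eqn{[0,1]}, `NA` invalid)
#'   and `valid`.
#' @export
coincidence_map <- function(rmap, neighborhood_radius_px) {
  rad <- as_radius_pair(neighborhood_radius_px, 0L, "neighborhood_radius_px")
  dims <- dim(rmap$r)
  if (sum(rmap$valid) == 0L) fi_stop("no valid frame-pair correlations")
  nr <- dims[2L]; nc <- dims[3L]
  csum <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (t in seq_len(dims[1L])) {
    rt <- rmap$r[t, , ]
    vt <- rmap$valid[t, , ]
    rt[!vt] <- 0
    csum <- csum + pmin(pmax(rt, 0), 1)
    cnt <- cnt + vt
  }
  bsum <- box_sum(csum, rad)$sum
  bcnt <- box_sum(cnt, rad)$sum
  valid <- bcnt > 0.5
  C <- matrix(NA_real_, nr, nc)
  C[valid] <- bsum[valid] / bcnt[valid]
  # guard against roundoff outside [0,1]
  C[valid] <- pmin(pmax(C[valid], 0), 1)
  list(coincidence = C, valid = valid)
}

# Convert a physical window size in mm to per-axis pixel radii:
# radius = round(mm / (2 * spacing)), at least 1 (full width 2r+1 is odd).
mm_to_radius_px <- function(size_mm, pixel_spacing_mm, min_allowed = 1L) {
  pmax(min_allowed, as.integer(round_half_up(size_mm / (2 * pixel_spacing_mm))))
}

#' Fit a fluctuation map to an ultrasound cine loop
#'
#' The central estimator of the package. For the first `n_frames` frames of
#' the clip it (1) optionally estimates and cancels bulk ROI motion
#' ([estimate_motion()], [compensate()]), (2) computes the local
#' cross-correlation coefficient R between every consecutive frame pair over
#' a window of physical size `window_mm` ([local_xcorr_pair()]), (3)
#' aggregates R into the degree of coincidence C over a spatial neighbourhood
#' of `neighborhood_mm` and all frame pairs ([coincidence_map()]), and (4)
#' derives the degree of fluctuation `F = 1 - C`, quantized to
#' `level = round(255 * F)` gradation levels. Validity masks (window support,
#' zero-variance windows, motion-compensation gaps, the ROI) are intersected
#' across all stages.
#'
#' Physical sizes are converted per axis via the pixel spacing:
#' `radius = round(mm / (2 * spacing))`, minimum 1 pixel.
#'
#' @param cine a [cine_loop()].
#' @param roi a [roi_mask()] matching the frame shape.
#' @param window_mm physical width of the correlation window (default 2 mm,
#'   the scale at which local speckle is compared between frames).
#' @param neighborhood_mm physical width of the coincidence neighbourhood
#'   (default 2 mm).
#' @param n_frames number of frames analysed (default 70; at the default
#'   20 fps that is 3.5 s). The first `n_frames` frames are used; fewer is an
#'   error.
#' @param motion logical, cancel bulk motion before correlation (default
#'   `TRUE`).
#' @param search_radius_px,subpixel motion-estimation settings, see
#'   [estimate_motion()].
#' @return An object of class `fluctmap` with fields `score` (F in
#'   \eqn{[0,1]}), `level` (integer 0-255), `coincidence` (C = 1 - F),
#'   `valid`, `roi`, `track` (the motion track or `NULL`), `frame0` (first
#'   frame, for display) and `params` (all effective settings).
#' @seealso [classify_lesion()], [plot.fluctmap()], [summary.fluctmap()]
#' @export
fluctmap <- function(cine, roi, window_mm = 2.0, neighborhood_mm = 2.0,
                     n_frames = 70L, motion = TRUE, search_radius_px = 8L,
                     subpixel = FALSE) {
  stopifnot(inherits(cine, "cine_loop"), inherits(roi, "roi_mask"))
  T_avail <- dim(cine$frames)[1L]
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) fi_stop("'n_frames' must be >= 2")
  if (T_avail < n_frames) {
    fi_stop(sprintf("insufficient frames: clip has %d, analysis needs %d",
                    T_avail, n_frames))
  }
  shp <- frame_shape(cine)
  if (!all(dim(roi$mask) == shp)) fi_stop("ROI shape does not match the frames")

  sub <- cine_loop(cine$frames[seq_len(n_frames), , , drop = FALSE],
                   cine$frame_rate_hz, cine$pixel_spacing_mm,
                   source_meta = cine$source_meta,
                   valid = if (is.null(cine$valid)) NULL else
                     cine$valid[seq_len(n_frames), , , drop = FALSE])

  track <- NULL
  if (isTRUE(motion)) {
    track <- estimate_motion(sub, roi, search_radius_px = search_radius_px,
                             subpixel = subpixel)
    sub <- compensate(sub, track)
  }

  wrad <- mm_to_radius_px(window_mm, cine$pixel_spacing_mm)
  nrad <- mm_to_radius_px(neighborhood_mm, cine$pixel_spacing_mm, min_allowed = 0L)

  rm_ <- rmap_consecutive(sub, roi, wrad)
  cm <- coincidence_map(rm_, nrad)

  valid <- cm$valid & roi$mask
  if (!any(valid)) fi_stop("ROI is empty after validity intersection")
  score <- matrix(NA_real_, shp[1L], shp[2L])
  score[valid] <- 1 - cm$coincidence[valid]
  level <- matrix(NA_integer_, shp[1L], shp[2L])
  level[valid] <- as.integer(round_half_up(255 * score[valid]))

  structure(
    list(score = score, level = level,
         coincidence = ifelse(valid, cm$coincidence, NA_real_),
         valid = valid, roi = roi, track = track,
         frame0 = cine$frames[1L, , ],
         params = list(window_mm = window_mm, neighborhood_mm = neighborhood_mm,
                       window_radius_px = wrad, neighborhood_radius_px = nrad,
                       n_frames = n_frames, motion = isTRUE(motion),
                       search_radius_px = as.integer(search_radius_px),
                       subpixel = isTRUE(subpixel),
                       frame_rate_hz = cine$frame_rate_hz,
                       pixel_spacing_mm = cine$pixel_spacing_mm)),
    class = "fluctmap")
}

#' @export
print.fluctmap <- function(x, ...) {
  p <- x$params
  cat(sprintf("fluctmap: %dx%d map, %d frames at %.4g fps\n",
              nrow(x$score), ncol(x$score), p$n_frames, p$frame_rate_hz))
  cat(sprintf("  window %.3g mm (radius %dx%d px), neighborhood %.3g mm (radius %dx%d px), motion %s\n",
              p$window_mm, p$window_radius_px[1L], p$window_radius_px[2L],
              p$neighborhood_mm, p$neighborhood_radius_px[1L],
              p$neighborhood_radius_px[2L],
              if (p$motion) "on" else "off"))
  v <- x$valid
  cat(sprintf("  %d valid px; fluctuation F: mean %.4f, max %.4f (levels %d..%d)\n",
              sum(v), mean(x$score[v]), max(x$score[v]),
              min(x$level[v]), max(x$level[v])))
  invisible(x)
}

#' Summarize a fluctuation map
#'
#' @param object a [fluctmap] object.
#' @param ... unused.
#' @return A list with validity counts, score quantiles, level histogram
#'   summaries and the effective parameters, of class `summary.fluctmap`.
#' @export
summary.fluctmap <- function(object, ...) {
  v <- object$valid
  s <- object$score[v]
  out <- list(
    n_roi_px = sum(object$roi$mask),
    n_valid_px = sum(v),
    score_mean = mean(s),
    score_quantiles = stats::quantile(s, c(0, 0.25, 0.5, 0.75, 1)),
    level_mean = mean(object$level[v]),
    frac_level_ge_170 = mean(object$level[v] >= 170L),
    max_displacement_px = if (is.null(object$track)) NA_real_ else
      max(abs(object$track$displacements)),
    params = object$params)
  class(out) <- "summary.fluctmap"
  out
}

#' @export
print.summary.fluctmap <- function(x, ...) {
  cat(sprintf("Fluctuation map over %d ROI px (%d valid)\n", x$n_roi_px, x$n_valid_px))
  cat(sprintf("  mean F = %.4f, median F = %.4f, max F = %.4f\n",
              x$score_mean, x$score_quantiles[[3L]], x$score_quantiles[[5L]]))
  cat(sprintf("  mean level = %.1f; fraction at yellow-red levels (>=170): %.4f\n",
              x$level_mean, x$frac_level_ge_170))
  if (!is.na(x$max_displacement_px)) {
    cat(sprintf("  motion compensation: max |d| = %.3g px\n", x$max_displacement_px))
  }
  invisible(x)
}
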