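#' Estimate bulk ROI motion by exhaustive block matching
#'
#' Breathing and cardiac pulsation translate the whole region of interest;
#' uncorrected, that bulk motion decorrelates consecutive frames and mimics
#' genuine internal fluctuation (the classic false-positive mechanism near the
#' diaphragm and heart). This estimator models one global 2D translation per
#' frame: the ROI patch of frame 0 is matched against every integer shift of
#' frame t within `search_radius_px` and the shift maximizing the normalized
#' cross-correlation (Pearson correlation over the ROI pixels) wins.
#'
#' Frame 0 is the fixed reference for every frame — clips are short (a few
#' seconds), so referencing frame 0 avoids drift accumulation that
#' frame-to-frame tracking would suffer. Ties are broken deterministically:
#' smallest displacement magnitude, then smallest row offset, then smallest
#' column offset. With `subpixel = TRUE` a 1D parabola is fitted through the
#' correlation scores around the integer peak in each axis and the refined
#' offset (clamped to half a pixel) is added.
#'
#' @param cine a [cine_loop()].
#' @param roi a [roi_mask()]; its bounding box plus the search radius must fit
#'   inside the frame.
#' @param search_radius_px maximum displacement searched, in pixels (>= 1).
#' @param subpixel logical; parabolic subpixel refinement of the peak.
#' @return An object of class `motion_track`: `displacements` is a T x 2
#'   matrix of (d_row, d_col) per frame relative to frame 0 (row 1 is (0,0)).
#' @export
estimate_motion <- function(cine, roi, search_radius_px = 8L, subpixel = FALSE) {
  stopifnot(inherits(cine, "cine_loop"), inherits(roi, "roi_mask"))
  s <- as.integer(search_radius_px)
  if (length(s) != 1L || is.na(s) || s < 1L) fi_stop("'search_radius_px' must be >= 1")
  shp <- frame_shape(cine)
  if (!identical(dim(roi$mask), as.integer(shp)) &&
      !identical(dim(roi$mask), shp)) {
    fi_stop("ROI mask shape does not match the frames")
  }
  bb <- roi$bounding_box  # 0-based half-open
  r0 <- bb[1L] + 1L; c0 <- bb[2L] + 1L; r1 <- bb[3L]; c1 <- bb[4L]
  if (r0 - s < 1L || c0 - s < 1L || r1 + s > shp[1L] || c1 + s > shp[2L]) {
    fi_stop("ROI bounding box plus search radius does not fit in the frame")
  }
  sub <- roi$mask[r0:r1, c0:c1]
  ref <- cine$frames[1L, , ][r0:r1, c0:c1][sub]
  refc <- ref - mean(ref)
  refss <- sum(refc^2)
  if (refss <= 1e-12) fi_stop("ROI patch of frame 0 has zero intensity variance")

  # candidate shifts in deterministic tie-break order
  grid <- expand.grid(dr = -s:s, dc = -s:s)
  ord <- order(grid$dr^2 + grid$dc^2, grid$dr, grid$dc)
  grid <- grid[ord, ]

  T <- n_frames(cine)
  disp <- matrix(0, T, 2L)
  for (t in seq_len(T)[-1L]) {
    ft <- cine$frames[t, , ]
    scores <- matrix(-Inf, 2L * s + 1L, 2L * s + 1L)  # indexed [dr+s+1, dc+s+1]
    best <- -Inf
    best_d <- c(0L, 0L)
    for (k in seq_len(nrow(grid))) {
      dr <- grid$dr[k]; dc <- grid$dc[k]
      patch <- ft[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc)][sub]
      pc <- patch - mean(patch)
      pss <- sum(pc^2)
      if (pss <= 1e-12) next
      ncc <- sum(refc * pc) / sqrt(refss * pss)
      scores[dr + s + 1L, dc + s + 1L] <- ncc
      if (ncc > best) {  # strict: first hit in tie-break order wins
        best <- ncc
        best_d <- c(dr, dc)
      }
    }
    if (!is.finite(best)) fi_stop(sprintf("no valid match for frame %d", t))
    d <- as.numeric(best_d)
    if (subpixel) {
      d <- d + parabolic_offset(scores, best_d[1L] + s + 1L, best_d[2L] + s + 1L)
      d <- pmin(pmax(d, -s), s)
    }
    disp[t, ] <- d
  }
  structure(list(displacements = disp, search_radius_px = s, subpixel = subpixel),
            class = "motion_track")
}

# 1D parabolic interpolation of the correlation peak along each axis.
parabolic_offset <- function(scores, i, j) {
  off <- c(0, 0)
  n <- nrow(scores)
  if (i > 1L && i < n) {
    sm <- scores[i - 1L, j]; s0 <- scores[i, j]; sp <- scores[i + 1L, j]
    den <- sm - 2 * s0 + sp
    if (is.finite(sm) && is.finite(sp) && den < -1e-12) {
      off[1L] <- max(-0.5, min(0.5, 0.5 * (sm - sp) / den))
    }
  }
  m <- ncol(scores)
  if (j > 1L && j < m) {
    sm <- scores[i, j - 1L]; s0 <- scores[i, j]; sp <- scores[i, j + 1L]
    den <- sm - 2 * s0 + sp
    if (is.finite(sm) && is.finite(sp) && den < -1e-12) {
      off[2L] <- max(-0.5, min(0.5, 0.5 * (sm - sp) / den))
    }
  }
  off
}

#' @export
print.motion_track <- function(x, ...) {
  mx <- max(abs(x$displacements))
  cat(sprintf("motion_track: %d frames, max |d| = %.3g px (search radius %d, subpixel %s)\n",
              nrow(x$displacements), mx, x$search_radius_px, x$subpixel))
  invisible(x)
}

#' Cancel estimated bulk motion
#'
#' Resamples every frame by the negative of its estimated displacement so the
#' scene is registered to frame 0. Integer displacements use exact
#' nearest-neighbour shifting; fractional displacements use bilinear
#' interpolation. Pixels whose source sample falls outside the frame carry no
#' data: they are set to 0 and flagged in the returned cine's `valid` array,
#' which downstream analysis intersects into its own validity masks.
#'
#' @param cine a [cine_loop()].
#' @param track a `motion_track` from [estimate_motion()] with one
#'   displacement per frame.
#' @return A [cine_loop()] with registered frames and a `valid` array.
#' @export
compensate <- function(cine, track) {
  stopifnot(inherits(cine, "cine_loop"), inherits(track, "motion_track"))
  T <- n_frames(cine)
  if (nrow(track$displacements) != T) {
    fi_stop("track length does not match frame count")
  }
  shp <- frame_shape(cine)
  nr <- shp[1L]; nc <- shp[2L]
  if (any(abs(track$displacements[, 1L]) >= nr) ||
      any(abs(track$displacements[, 2L]) >= nc)) {
    fi_stop("displacement exceeds frame size")
  }
  out <- cine$frames
  vin <- cine$valid
  vout <- array(TRUE, dim(cine$frames))
  if (!is.null(vin)) vout <- vin
  for (t in seq_len(T)) {
    d <- track$displacements[t, ]
    if (all(d == 0)) next
    f <- cine$frames[t, , ]
    v <- if (is.null(vin)) matrix(TRUE, nr, nc) else vin[t, , ]
    res <- shift_sample(f, v, d)
    out[t, , ] <- res$f
    vout[t, , ] <- res$v
  }
  cine_loop(out, cine$frame_rate_hz, cine$pixel_spacing_mm,
            source_meta = c(cine$source_meta, list(motion_compensated = TRUE)),
            valid = vout)
}

# Sample f at (i + dr, j + dc); nearest-neighbour for integer d, bilinear
# otherwise. Returns the resampled frame and its validity.
shift_sample <- function(f, v, d) {
  nr <- nrow(f); nc <- ncol(f)
  dr <- d[1L]; dc <- d[2L]
  if (abs(dr - round(dr)) < 1e-9 && abs(dc - round(dc)) < 1e-9) {
    dr <- as.integer(round(dr)); dc <- as.integer(round(dc))
    of <- matrix(0, nr, nc)
    ov <- matrix(FALSE, nr, nc)
    i1 <- max(1L, 1L - dr); i2 <- min(nr, nr - dr)
    j1 <- max(1L, 1L - dc); j2 <- min(nc, nc - dc)
    if (i1 <= i2 && j1 <= j2) {
      of[i1:i2, j1:j2] <- f[(i1 + dr):(i2 + dr), (j1 + dc):(j2 + dc)]
      ov[i1:i2, j1:j2] <- v[(i1 + dr):(i2 + dr), (j1 + dc):(j2 + dc)]
    }
    return(list(f = of, v = ov))
  }
  si <- matrix(rep(seq_len(nr) + dr, nc), nr, nc)
  sj <- matrix(rep(seq_len(nc) + dc, each = nr), nr, nc)
  i0 <- floor(si); j0 <- floor(sj)
  wi <- si - i0; wj <- sj - j0
  ok <- i0 >= 1 & i0 + 1 <= nr & j0 >= 1 & j0 + 1 <= nc
  of <- matrix(0, nr, nc)
  ov <- matrix(FALSE, nr, nc)
  idx <- function(ii, jj) (jj - 1L) * nr + ii
  w <- which(ok)
  if (length(w)) {
    i0w <- i0[w]; j0w <- j0[w]; wiw <- wi[w]; wjw <- wj[w]
    f00 <- f[idx(i0w, j0w)];     f01 <- f[idx(i0w, j0w + 1L)]
    f10 <- f[idx(i0w + 1L, j0w)]; f11 <- f[idx(i0w + 1L, j0w + 1L)]
    of[w] <- (1 - wiw) * (1 - wjw) * f00 + (1 - wiw) * wjw * f01 +
      wiw * (1 - wjw) * f10 + wiw * wjw * f11
    ov[w] <- v[idx(i0w, j0w)] & v[idx(i0w, j0w + 1L)] &
      v[idx(i0w + 1L, j0w)] & v[idx(i0w + 1L, j0w + 1L)]
  }
  list(f = of, v = ov)
}
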