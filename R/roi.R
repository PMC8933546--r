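#' Region-of-interest masks
#'
#' An ROI is a boolean pixel mask over the frame grid together with the tight
#' bounding box of its true pixels. Throughout the package coordinates are
#' 0-based in (row, col) order and rectangles are half-open:
#' `(row0, col0, row1, col1)` covers rows `row0 .. row1-1` and columns
#' `col0 .. col1-1`.
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @return An object of class `roi_mask` with fields `mask` and
#'   `bounding_box` (0-based, half-open).
#' @export
roi_mask <- function(mask) {
  if (!is.logical(mask) || !is.matrix(mask)) fi_stop("'mask' must be a logical matrix")
  if (!any(mask)) fi_stop("ROI mask has no true pixels")
  idx <- which(mask, arr.ind = TRUE)
  bb <- c(min(idx[, 1L]) - 1L, min(idx[, 2L]) - 1L, max(idx[, 1L]), max(idx[, 2L]))
  structure(list(mask = mask, bounding_box = as.integer(bb)), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  bb <- x$bounding_box
  cat(sprintf("roi_mask: %d px on %dx%d grid, bbox (%d,%d,%d,%d) [0-based, half-open]\n",
              sum(x$mask), nrow(x$mask), ncol(x$mask), bb[1L], bb[2L], bb[3L], bb[4L]))
  invisible(x)
}

#' Rectangular ROI
#'
#' @param row0,col0,row1,col1 0-based half-open rectangle bounds.
#' @param shape (rows, cols) of the frame grid.
#' @return A [roi_mask()].
#' @export
roi_rect <- function(row0, col0, row1, col1, shape) {
  if (row0 < 0 || col0 < 0 || row1 > shape[1L] || col1 > shape[2L] ||
      row1 <= row0 || col1 <= col0) {
    fi_stop("rectangle is empty or outside the frame")
  }
  m <- matrix(FALSE, shape[1L], shape[2L])
  m[(row0 + 1L):row1, (col0 + 1L):col1] <- TRUE
  roi_mask(m)
}

#' Polygonal ROI
#'
#' Rasterizes a polygon by the even-odd (crossing-number) rule evaluated at
#' pixel centers, with vertices in 0-based (row, col) pixel coordinates.
#'
#' @param vertices numeric matrix or list of (row, col) vertices.
#' @param shape (rows, cols) of the frame grid.
#' @return A [roi_mask()].
#' @export
roi_polygon <- function(vertices, shape) {
  v <- if (is.matrix(vertices)) vertices else do.call(rbind, vertices)
  if (nrow(v) < 3L) fi_stop("polygon needs >= 3 vertices")
  if (any(v[, 1L] < 0) || any(v[, 2L] < 0) ||
      any(v[, 1L] > shape[1L] - 1L) || any(v[, 2L] > shape[2L] - 1L)) {
    fi_stop("polygon vertices outside the frame")
  }
  nr <- shape[1L]; nc <- shape[2L]
  py <- matrix(rep(0:(nr - 1L), nc), nr, nc)          # pixel-center rows
  px <- matrix(rep(0:(nc - 1L), each = nr), nr, nc)   # pixel-center cols
  inside <- matrix(FALSE, nr, nc)
  nv <- nrow(v)
  jprev <- nv
  for (k in seq_len(nv)) {
    y1 <- v[k, 1L]; x1 <- v[k, 2L]
    y2 <- v[jprev, 1L]; x2 <- v[jprev, 2L]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    jprev <- k
  }
  if (!any(inside)) fi_stop("polygon rasterizes to an empty mask")
  roi_mask(inside)
}

#' Read an ROI from JSON
#'
#' The JSON is either
#' `{"type":"rect","row0":..,"col0":..,"row1":..,"col1":..}` (0-based,
#' half-open) or `{"type":"polygon","vertices":[[r,c],...]}` with vertices in
#' 0-based pixel coordinates (filled by the even-odd rule).
#'
#' @param path JSON file path.
#' @param frame_shape (rows, cols) of the frames the ROI applies to.
#' @return A [roi_mask()].
#' @export
read_roi <- function(path, frame_shape) {
  if (!file.exists(path)) fi_stop(sprintf("ROI file '%s' does not exist", path))
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(spec$type)) fi_stop("ROI JSON must have a 'type' field")
  switch(spec$type,
    rect = roi_rect(spec$row0, spec$col0, spec$row1, spec$col1, frame_shape),
    polygon = roi_polygon(as.matrix(spec$vertices), frame_shape),
    fi_stop(sprintf("unknown ROI type '%s'", spec$type)))
}

#' Write an ROI specification to JSON
#'
#' @param spec a list as accepted by [read_roi()] (fields `type`, etc.).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roi <- function(spec, path) {
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
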