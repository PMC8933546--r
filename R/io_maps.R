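# Saving and loading fluctuation maps, level maps, masks and overlays.

#' Write a fluctuation score map
#'
#' The continuous score is written losslessly: 32-bit float TIFF (`.tif`) or
#' RDS doubles (`.rds`). Invalid pixels are written as 0 in TIFF (floats in
#' the file must lie in \[0,1\]); the validity mask should be saved alongside
#' when it matters, which [run_analyze()] does via its summary JSON.
#'
#' @param map numeric matrix in \eqn{[0,1]} (or a [fluctmap] object, whose
#'   `score` is written).
#' @param path output path (`.tif`, `.tiff` or `.rds`).
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  if (inherits(map, "fluctmap")) {
    m <- map$score
    m[!map$valid] <- 0
    map <- m
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(map, path, bits.per.sample = 32L)
  } else if (ext == "rds") {
    saveRDS(map, path)
  } else {
    fi_stop("write_map supports .tif/.tiff and .rds")
  }
  invisible(path)
}

#' Read a fluctuation score map written by [write_map()]
#'
#' @param path `.tif`/`.tiff` or `.rds` path.
#' @return A numeric matrix.
#' @export
read_map <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    m
  } else if (ext == "rds") {
    readRDS(path)
  } else {
    fi_stop("read_map supports .tif/.tiff and .rds")
  }
}

#' Write a 0-255 level map as an 8-bit grayscale PNG
#'
#' @param level integer matrix with values in 0..255.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_level_png <- function(level, path) {
  if (min(level) < 0 || max(level) > 255) fi_stop("levels must be in 0..255")
  png::writePNG(level / 255, path)
  invisible(path)
}

#' Read an 8-bit grayscale PNG back to 0-255 integer levels
#'
#' @param path PNG path.
#' @return Integer matrix in 0..255.
#' @export
read_level_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round_half_up(m * 255)), nrow(m), ncol(m))
}

#' Write a boolean mask as a black/white PNG
#'
#' @param mask logical matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Read a black/white PNG as a boolean mask
#'
#' Any pixel with intensity > 0.5 is `TRUE`.
#'
#' @param path PNG path.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m > 0.5
}

#' Write an RGB overlay image as PNG
#'
#' @param rgb integer array rows x cols x 3 with values 0..255 (as produced by
#'   [overlay_frame()]).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(rgb, path) {
  if (min(rgb) < 0 || max(rgb) > 255) fi_stop("overlay channels must be in 0..255")
  png::writePNG(rgb / 255, path)
  invisible(path)
}
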