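#' Construct a cine loop
#'
#' A cine loop is an ordered stack of grayscale frames together with its
#' physical calibration: the frame rate and the pixel spacing. All analysis in
#' the package operates on this container. Intensities are expected in
#' \eqn{[0,1]}; use [read_cine()] to load and normalize external data.
#'
#' @param frames 3D numeric array, time x rows x cols, values in \eqn{[0,1]}.
#' @param frame_rate_hz frame rate in frames per second (> 0).
#' @param pixel_spacing_mm length-2 numeric, (row, col) spacing in mm/pixel.
#' @param source_meta optional list of free-form provenance information.
#' @param valid optional logical array of the same dimension marking pixels
#'   that carry real data (used by motion compensation to flag pixels sampled
#'   from outside the frame). `NULL` means all pixels are valid.
#' @return An object of class `cine_loop`.
#' @export
cine_loop <- function(frames, frame_rate_hz, pixel_spacing_mm,
                      source_meta = list(), valid = NULL) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    fi_stop("'frames' must be a 3D array (time x rows x cols)")
  }
  if (dim(frames)[1L] < 2L) fi_stop("a cine loop needs at least 2 frames")
  if (anyNA(frames) || any(!is.finite(frames))) {
    fi_stop("frame intensities must be finite")
  }
  if (min(frames) < -1e-9 || max(frames) > 1 + 1e-9) {
    fi_stop("frame intensities must lie in [0,1]; normalize on load")
  }
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1L ||
      !is.finite(frame_rate_hz) || frame_rate_hz <= 0) {
    fi_stop("'frame_rate_hz' must be a single positive number")
  }
  pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
  if (length(pixel_spacing_mm) == 1L) {
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  }
  if (length(pixel_spacing_mm) != 2L || any(!is.finite(pixel_spacing_mm)) ||
      any(pixel_spacing_mm <= 0)) {
    fi_stop("'pixel_spacing_mm' must be two positive numbers (row, col)")
  }
  if (!is.null(valid)) {
    if (!is.logical(valid) || !identical(dim(valid), dim(frames))) {
      fi_stop("'valid' must be a logical array matching 'frames'")
    }
  }
  structure(
    list(frames = frames, frame_rate_hz = frame_rate_hz,
         pixel_spacing_mm = pixel_spacing_mm, source_meta = source_meta,
         valid = valid),
    class = "cine_loop"
  )
}

#' @export
print.cine_loop <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "cine_loop: %d frames of %dx%d px, %.4g fps (%.3g s), spacing %.4g x %.4g mm/px\n",
    d[1L], d[2L], d[3L], x$frame_rate_hz, d[1L] / x$frame_rate_hz,
    x$pixel_spacing_mm[1L], x$pixel_spacing_mm[2L]))
  if (!is.null(x$valid)) {
    cat(sprintf("  validity mask present (%.1f%% valid)\n", 100 * mean(x$valid)))
  }
  invisible(x)
}

#' @export
dim.cine_loop <- function(x) dim(x$frames)

n_frames <- function(cine) dim(cine$frames)[1L]
frame_shape <- function(cine) dim(cine$frames)[2:3]

# Min-max normalize a stack to [0,1]; a constant stack maps to 0.
normalize01 <- function(x) {
  lo <- min(x)
  hi <- max(x)
  if (hi - lo <= 0) return(x * 0)
  (x - lo) / (hi - lo)
}

# Standard Rec.601 luma conversion for color inputs.
to_luma <- function(arr3) {
  0.299 * arr3[, , 1L] + 0.587 * arr3[, , 2L] + 0.114 * arr3[, , 3L]
}

read_image_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    fi_stop(sprintf("unsupported frame image format: '%s'", ext)))
  if (length(dim(img)) == 3L) img <- to_luma(img)
  img
}

#' Read a cine loop
#'
#' Supported containers:
#' \itemize{
#'   \item a multi-page TIFF file (8/16-bit integer or 32-bit float pages);
#'   \item a directory of equally-sized PNG or TIFF frames, read in
#'     lexicographic filename order;
#'   \item an RDS file holding a 3D numeric array (time x rows x cols) or a
#'     `cine_loop` object — the package's lossless raw-stack container.
#' }
#' DICOM and AVI/MP4 video are not supported by this build; export frames to
#' one of the containers above. Intensities are min-max normalized to
#' \eqn{[0,1]} per clip (the fluctuation statistic is invariant under positive
#' linear intensity maps, so this cannot change results); color frames are
#' converted to grayscale by Rec.601 luma weights.
#'
#' Calibration must come from somewhere: an RDS `cine_loop` carries its own,
#' every other container requires both overrides. Missing calibration is an
#' error, because the ~2 mm analysis window is specified in millimetres.
#'
#' @param path file or directory to read.
#' @param pixel_spacing_mm optional (row, col) mm/pixel override.
#' @param frame_rate_hz optional frame-rate override in Hz.
#' @return A [cine_loop()].
#' @export
read_cine <- function(path, pixel_spacing_mm = NULL, frame_rate_hz = NULL) {
  if (!file.exists(path)) fi_stop(sprintf("input '%s' does not exist", path))
  meta <- list(path = path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                        full.names = TRUE)
    files <- sort(files)
    if (length(files) < 2L) fi_stop("frame directory must contain >= 2 PNG/TIFF frames")
    imgs <- lapply(files, read_image_gray)
    shp <- dim(imgs[[1L]])
    if (!all(vapply(imgs, function(m) identical(dim(m), shp), logical(1L)))) {
      fi_stop("frames in directory have inconsistent shapes")
    }
    frames <- aperm(array(unlist(imgs), dim = c(shp, length(imgs))), c(3L, 1L, 2L))
    meta$container <- "frame_directory"
  } else {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) {
      pages <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      if (length(pages) < 2L) fi_stop("multi-page TIFF must contain >= 2 frames")
      pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) to_luma(p) else p)
      shp <- dim(pages[[1L]])
      if (!all(vapply(pages, function(m) identical(dim(m), shp), logical(1L)))) {
        fi_stop("TIFF pages have inconsistent shapes")
      }
      frames <- aperm(array(unlist(pages), dim = c(shp, length(pages))), c(3L, 1L, 2L))
      meta$container <- "multipage_tiff"
    } else if (ext == "rds") {
      obj <- readRDS(path)
      if (inherits(obj, "cine_loop")) {
        if (is.null(pixel_spacing_mm)) pixel_spacing_mm <- obj$pixel_spacing_mm
        if (is.null(frame_rate_hz)) frame_rate_hz <- obj$frame_rate_hz
        frames <- obj$frames
        meta <- c(meta, obj$source_meta)
      } else if (is.array(obj) && length(dim(obj)) == 3L) {
        frames <- obj
      } else {
        fi_stop("RDS cine must hold a 3D array or a cine_loop")
      }
      meta$container <- "rds_stack"
    } else if (ext %in% c("dcm", "dicom", "avi", "mp4", "mov")) {
      fi_stop(sprintf(
        "container '.%s' is not supported by this build; export frames to multi-page TIFF, a PNG/TIFF directory, or an RDS stack",
        ext))
    } else {
      fi_stop(sprintf("unrecognized cine container: '%s'", path))
    }
  }
  if (is.null(pixel_spacing_mm)) {
    fi_stop("pixel spacing unknown: supply 'pixel_spacing_mm' (mm/pixel)")
  }
  if (is.null(frame_rate_hz)) {
    fi_stop("frame rate unknown: supply 'frame_rate_hz'")
  }
  cine_loop(normalize01(frames), frame_rate_hz, pixel_spacing_mm, source_meta = meta)
}

#' Write a cine loop
#'
#' Writes either a multi-page 32-bit float TIFF (portable, float32 precision)
#' or an RDS file (lossless doubles, carries calibration). The container is
#' chosen by the file extension.
#'
#' @param cine a [cine_loop()].
#' @param path output path ending in `.tif`/`.tiff` or `.rds`.
#' @return `path`, invisibly.
#' @export
write_cine <- function(cine, path) {
  stopifnot(inherits(cine, "cine_loop"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- lapply(seq_len(n_frames(cine)), function(t) cine$frames[t, , ])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else if (ext == "rds") {
    saveRDS(cine, path)
  } else {
    fi_stop("write_cine supports .tif/.tiff and .rds")
  }
  invisible(path)
}
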