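#' Specification of a synthetic speckle cine loop
#'
#' The simulator produces ultrasound-like B-mode cine loops from a first-order
#' speckle model: a complex circular-Gaussian scatterer field is convolved
#' with a separable Gaussian point-spread function and the envelope magnitude
#' is taken as the image (fully developed speckle; the envelope is
#' Rayleigh-distributed with point SNR \eqn{\sqrt{\pi/(4-\pi)} \approx 1.91}).
#' Inside each *flutter region* the complex field decorrelates frame to frame
#' as an AR(1) process, \eqn{z_t = \rho z_{t-1} + \sqrt{1-\rho^2}\, w_t} with
#' fresh white noise \eqn{w_t}; outside, the field is static. `rho = 1` means
#' no decorrelation (static control), `rho = 0` fully independent frames.
#' Optionally a global sinusoidal translation emulates cardiac pulsation (the
#' false-positive mechanism that motion compensation exists to cancel) and
#' additive Gaussian noise emulates electronic noise.
#'
#' @param shape (T, rows, cols) of the clip (default 70 x 64 x 64).
#' @param pixel_spacing_mm (row, col) mm/pixel (default 0.2, a typical
#'   linear-probe resolution).
#' @param frame_rate_hz frames per second (default 20).
#' @param psf_sigma_px Gaussian PSF sigmas (axial = row, lateral = col) in
#'   pixels (default 1.5, 2.0).
#' @param flutter_regions list of `list(mask = <logical matrix>, rho = <0..1>)`.
#' @param pulsation `NULL`, or `c(amplitude_px, frequency_hz)` for a global
#'   sinusoidal translation along rows; displacements are rounded to whole
#'   pixels (applied circularly) so the artifact is pure bulk translation.
#' @param noise_sigma additive Gaussian intensity noise sd (default 0.01 on
#'   the \eqn{[0,1]} scale).
#' @param log_compress logical; apply a log transform to the envelope before
#'   normalization (off by default — the correlation statistic is invariant
#'   to monotone linear maps, and linear envelope keeps the Rayleigh checks
#'   exact).
#' @param seed integer RNG seed; fixed seed gives bit-reproducible clips.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(shape = c(70L, 64L, 64L),
                           pixel_spacing_mm = c(0.2, 0.2),
                           frame_rate_hz = 20,
                           psf_sigma_px = c(1.5, 2.0),
                           flutter_regions = list(),
                           pulsation = NULL,
                           noise_sigma = 0.01,
                           log_compress = FALSE,
                           seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L) || shape[1L] < 2L) {
    fi_stop("'shape' must be (T >= 2, rows, cols)")
  }
  for (fr in flutter_regions) {
    if (is.null(fr$mask) || is.null(fr$rho)) {
      fi_stop("each flutter region needs 'mask' and 'rho'")
    }
    if (!identical(dim(fr$mask), shape[2:3])) fi_stop("flutter mask shape mismatch")
    if (fr$rho < 0 || fr$rho > 1) fi_stop("'rho' must be in [0,1]")
  }
  if (!is.null(pulsation)) {
    if (length(pulsation) != 2L || any(pulsation < 0)) {
      fi_stop("'pulsation' must be c(amplitude_px, frequency_hz)")
    }
  }
  structure(list(shape = shape, pixel_spacing_mm = pixel_spacing_mm,
                 frame_rate_hz = frame_rate_hz, psf_sigma_px = psf_sigma_px,
                 flutter_regions = flutter_regions, pulsation = pulsation,
                 noise_sigma = noise_sigma, log_compress = log_compress,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Separable Gaussian blur with truncated, renormalized kernels at the border.
gauss_blur <- function(m, sigma) {
  for (axis in 1:2) {
    s <- sigma[axis]
    if (s <= 0) next
    n <- if (axis == 1L) nrow(m) else ncol(m)
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s)
    K <- matrix(0, n, n)
    for (o in -r:r) {
      i <- seq_len(n)
      j <- i + o
      ok <- j >= 1L & j <= n
      K[cbind(i[ok], j[ok])] <- k[o + r + 1L]
    }
    K <- K / rowSums(K)
    m <- if (axis == 1L) K %*% m else m %*% t(K)
  }
  m
}

circ_shift_rows <- function(m, d) {
  if (d == 0L) return(m)
  n <- nrow(m)
  m[((seq_len(n) - 1L + d) %% n) + 1L, , drop = FALSE]
}

#' Simulate a synthetic speckle cine loop
#'
#' Draws the scatterer fields, applies the PSF and envelope detection,
#' normalizes the clip to \eqn{[0,1]}, applies pulsation shifts and additive
#' noise per the spec, and returns the clip together with the ground-truth
#' flutter mask. With a fixed seed the output is bit-reproducible, and the
#' caller's RNG state is left untouched.
#'
#' @param spec a [synthetic_spec()].
#' @param keep_field logical; also return the raw (pre-PSF) complex scatterer
#'   field as `field_re`/`field_im` arrays, for diagnostics on the underlying
#'   decorrelation process.
#' @return A list with `cine` (a [cine_loop()]), `flutter_mask` (logical
#'   matrix, union of the flutter regions) and, if requested, the raw field.
#' @export
simulate_cine <- function(spec, keep_field = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  T <- spec$shape[1L]; nr <- spec$shape[2L]; nc <- spec$shape[3L]
  masks <- lapply(spec$flutter_regions, `[[`, "mask")
  rhos <- vapply(spec$flutter_regions, `[[`, numeric(1L), "rho")
  flutter_mask <- matrix(FALSE, nr, nc)
  for (m in masks) flutter_mask <- flutter_mask | m

  res <- with_seed(spec$seed, {
    zr <- matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(2)), nr, nc)
    zi <- matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(2)), nr, nc)
    env <- array(0, c(T, nr, nc))
    fr_re <- if (keep_field) array(0, c(T, nr, nc)) else NULL
    fr_im <- if (keep_field) array(0, c(T, nr, nc)) else NULL
    for (t in seq_len(T)) {
      if (t > 1L) {
        for (k in seq_along(masks)) {
          idx <- which(masks[[k]])
          if (!length(idx)) next
          rho <- rhos[k]
          wr <- stats::rnorm(length(idx), sd = 1 / sqrt(2))
          wi <- stats::rnorm(length(idx), sd = 1 / sqrt(2))
          zr[idx] <- rho * zr[idx] + sqrt(1 - rho^2) * wr
          zi[idx] <- rho * zi[idx] + sqrt(1 - rho^2) * wi
        }
      }
      if (keep_field) {
        fr_re[t, , ] <- zr
        fr_im[t, , ] <- zi
      }
      br <- gauss_blur(zr, spec$psf_sigma_px)
      bi <- gauss_blur(zi, spec$psf_sigma_px)
      env[t, , ] <- sqrt(br^2 + bi^2)
    }
    if (spec$log_compress) env <- log1p(env)
    env <- normalize01(env)
    if (!is.null(spec$pulsation)) {
      amp <- spec$pulsation[1L]; freq <- spec$pulsation[2L]
      for (t in seq_len(T)) {
        d <- as.integer(round(amp * sin(2 * pi * freq * (t - 1L) / spec$frame_rate_hz)))
        env[t, , ] <- circ_shift_rows(env[t, , ], d)
      }
    }
    if (spec$noise_sigma > 0) {
      env <- env + array(stats::rnorm(length(env), sd = spec$noise_sigma), dim(env))
      env <- pmin(pmax(env, 0), 1)
    }
    list(env = env, fr_re = fr_re, fr_im = fr_im)
  })

  cine <- cine_loop(res$env, spec$frame_rate_hz, spec$pixel_spacing_mm,
                    source_meta = list(synthetic = TRUE, seed = spec$seed))
  out <- list(cine = cine, flutter_mask = flutter_mask)
  if (keep_field) {
    out$field_re <- res$fr_re
    out$field_im <- res$fr_im
  }
  out
}

#' Disc mask helper
#'
#' @param shape (rows, cols).
#' @param center (row, col) center, 1-based.
#' @param radius_px radius in pixels.
#' @return Logical matrix.
#' @export
disc_mask <- function(shape, center, radius_px) {
  rr <- matrix(rep(seq_len(shape[1L]), shape[2L]), shape[1L], shape[2L])
  cc <- matrix(rep(seq_len(shape[2L]), each = shape[1L]), shape[1L], shape[2L])
  (rr - center[1L])^2 + (cc - center[2L])^2 <= radius_px^2
}

#' Canonical synthetic scenarios
#'
#' Four presets cover the study conditions every stage is validated against:
#' `static` (no flutter, noise only), `flutter` (an AR(1) rho = 0.9 disc of
#' 12 px radius in static speckle), `pulsation` (global sinusoidal
#' translation, 2 px amplitude at 1 Hz — a cardiac-rate artifact) and `both`.
#' All presets are 70 frames at 20 fps (the 3.5 s analysis budget), 64x64 px
#' at 0.2 mm/pixel, with additive noise sd 0.01. Each preset carries a
#' lesion mask (the disc) and a rectangular ROI of about twice the lesion
#' area, following the guidance that analysis needs comparison tissue of
#' roughly the lesion's own size.
#'
#' @param name one of `"static"`, `"flutter"`, `"pulsation"`, `"both"`.
#' @param seed RNG seed.
#' @param rho flutter AR(1) correlation used by the flutter presets
#'   (default 0.9).
#' @return A list with `spec` ([synthetic_spec()]), `roi` ([roi_mask()]),
#'   `lesion_mask` (logical matrix) and `name`.
#' @export
synthetic_preset <- function(name = c("static", "flutter", "pulsation", "both"),
                             seed = 1L, rho = 0.9) {
  name <- match.arg(name)
  shape <- c(70L, 64L, 64L)
  disc <- disc_mask(shape[2:3], c(32, 32), 12)
  flutter <- if (name %in% c("flutter", "both")) {
    list(list(mask = disc, rho = rho))
  } else {
    list()
  }
  pulsation <- if (name %in% c("pulsation", "both")) c(2, 1) else NULL
  spec <- synthetic_spec(shape = shape, flutter_regions = flutter,
                         pulsation = pulsation, seed = seed)
  # ROI: centered square of ~2x the disc area (pi*12^2 ~ 452 px -> 30x30 box)
  roi <- roi_rect(17L, 17L, 47L, 47L, shape[2:3])
  list(spec = spec, roi = roi, lesion_mask = disc, name = name)
}

#' Write the canonical fixture suite to disk
#'
#' Writes the four [synthetic_preset()] clips (70 frames, 20 fps) as
#' multi-page float TIFFs with their ROI JSONs, lesion and ground-truth
#' flutter masks (PNG), plus a `manifest.json` recording seeds and all
#' generator parameters. Regenerating with the same seed reproduces the files
#' bit-identically.
#'
#' @param out_dir output directory (created if missing).
#' @param seed base RNG seed; preset k uses `seed + k - 1`.
#' @return Named list of per-preset file paths, invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) fi_stop(sprintf("cannot create '%s'", out_dir))
  presets <- c("static", "flutter", "pulsation", "both")
  manifest <- list(base_seed = seed, clips = list())
  paths <- list()
  for (k in seq_along(presets)) {
    nm <- presets[k]
    ps <- synthetic_preset(nm, seed = seed + k - 1L)
    sim <- simulate_cine(ps$spec)
    clip <- file.path(out_dir, paste0(nm, ".tif"))
    write_cine(sim$cine, clip)
    roi_path <- file.path(out_dir, paste0(nm, "_roi.json"))
    bb <- ps$roi$bounding_box
    write_roi(list(type = "rect", row0 = bb[1L], col0 = bb[2L],
                   row1 = bb[3L], col1 = bb[4L]), roi_path)
    lesion_path <- file.path(out_dir, paste0(nm, "_lesion.png"))
    write_mask_png(ps$lesion_mask, lesion_path)
    fl_path <- file.path(out_dir, paste0(nm, "_flutter_truth.png"))
    write_mask_png(sim$flutter_mask, fl_path)
    manifest$clips[[nm]] <- list(
      file = basename(clip), seed = ps$spec$seed,
      shape = ps$spec$shape, frame_rate_hz = ps$spec$frame_rate_hz,
      pixel_spacing_mm = ps$spec$pixel_spacing_mm,
      psf_sigma_px = ps$spec$psf_sigma_px,
      noise_sigma = ps$spec$noise_sigma,
      rho = if (length(ps$spec$flutter_regions)) ps$spec$flutter_regions[[1L]]$rho else NULL,
      pulsation = ps$spec$pulsation)
    paths[[nm]] <- list(clip = clip, roi = roi_path, lesion = lesion_path,
                        flutter_truth = fl_path)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
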