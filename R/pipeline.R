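default_config <- function() {
  list(
    input = NULL,
    roi = NULL,
    lesion_mask = NULL,
    out_prefix = NULL,
    pixel_spacing_mm = NULL,
    frame_rate_hz = NULL,
    n_frames = 70L,
    window_mm = 2.0,
    neighborhood_mm = 2.0,
    motion = TRUE,
    search_radius_px = 8L,
    subpixel = FALSE,
    alpha = 0.5,
    palette = "fluct",
    display_min_level = 64L,
    level_threshold = 170L,
    min_fraction = 0.05,
    min_component_px = 25L,
    seed = NULL)
}

#' Build an analysis configuration
#'
#' Merges user settings over the package defaults (70 frames at 20 fps, 2 mm
#' window and neighbourhood, motion compensation on, display threshold 64,
#' detection thresholds 170 / 0.05 / 25 px). Unknown keys are rejected so a
#' typo cannot silently fall back to a default. `config` may be a named list
#' or a path to a JSON or YAML file; named `...` arguments override it.
#'
#' @param config named list, or JSON/YAML file path, of settings.
#' @param ... individual settings overriding `config`.
#' @return A validated config list of class `analysis_config`.
#' @export
analysis_config <- function(config = list(), ...) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) fi_stop(sprintf("config file '%s' does not exist", config))
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yml", "yaml")) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        fi_stop("YAML config requires the 'yaml' package")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  over <- list(...)
  cfg <- default_config()
  for (src in list(config, over)) {
    if (!length(src)) next
    if (is.null(names(src)) || any(names(src) == "")) {
      fi_stop("config entries must be named")
    }
    unknown <- setdiff(names(src), names(cfg))
    if (length(unknown)) {
      fi_stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
    }
    cfg[names(src)] <- src
  }
  structure(cfg, class = "analysis_config")
}

#' Run the full analysis pipeline
#'
#' Load -> motion compensation -> fluctuation map -> overlay rendering ->
#' lesion call, driven by an [analysis_config()]. When `out_prefix` is set,
#' writes `<prefix>_score.tif` (lossless float score), `<prefix>_level.png`
#' (8-bit levels), `<prefix>_overlay.png`, `<prefix>_track.json` (motion
#' track, when motion is on) and `<prefix>_summary.json` carrying the call,
#' the colored fraction, validity statistics and every effective parameter,
#' so a run can be replayed exactly.
#'
#' When the ROI covers less than twice the lesion area a warning is issued
#' (and recorded in the summary): the analysis needs surrounding tissue of
#' about the lesion's own size for comparison.
#'
#' If no lesion mask is supplied the call is evaluated over the whole ROI.
#'
#' @param config an [analysis_config()], or anything accepted by it.
#' @param cine optionally, an in-memory [cine_loop()] to analyse instead of
#'   reading `config$input`.
#' @return The summary list, invisibly (class `fluct_analysis`), with the
#'   fitted [fluctmap] attached as attribute `"fmap"`.
#' @export
run_analyze <- function(config, cine = NULL) {
  if (!inherits(config, "analysis_config")) config <- analysis_config(config)
  if (is.null(cine)) {
    if (is.null(config$input)) fi_stop("config$input is required")
    cine <- read_cine(config$input,
                      pixel_spacing_mm = config$pixel_spacing_mm,
                      frame_rate_hz = config$frame_rate_hz)
  }
  shp <- dim(cine$frames)[2:3]
  roi <- config$roi
  if (is.null(roi)) fi_stop("config$roi is required")
  if (is.character(roi)) roi <- read_roi(roi, shp)
  if (!inherits(roi, "roi_mask")) fi_stop("'roi' must be a roi_mask or a JSON path")

  lesion <- config$lesion_mask
  if (is.character(lesion)) {
    lesion <- if (tolower(tools::file_ext(lesion)) == "json") {
      read_roi(lesion, shp)$mask
    } else {
      read_mask_png(lesion)
    }
  }
  if (inherits(lesion, "roi_mask")) lesion <- lesion$mask

  warnings <- character(0)
  if (!is.null(lesion) && sum(roi$mask) < 2 * sum(lesion)) {
    w <- sprintf(
      "ROI area (%d px) is smaller than twice the lesion area (%d px); include comparison tissue of about the lesion's own size",
      sum(roi$mask), sum(lesion))
    warning(w, call. = FALSE)
    warnings <- c(warnings, w)
  }

  fm <- fluctmap(cine, roi,
                 window_mm = config$window_mm,
                 neighborhood_mm = config$neighborhood_mm,
                 n_frames = config$n_frames,
                 motion = config$motion,
                 search_radius_px = config$search_radius_px,
                 subpixel = config$subpixel)

  call_mask <- if (is.null(lesion)) roi$mask else lesion
  call <- classify_lesion(fm, call_mask,
                          level_threshold = config$level_threshold,
                          min_fraction = config$min_fraction,
                          min_component_px = config$min_component_px)

  v <- fm$valid
  summary <- list(
    positive = call$positive,
    colored_fraction = call$colored_fraction,
    largest_component_px = call$largest_component_px,
    lesion_mask_used = !is.null(lesion),
    n_roi_px = sum(roi$mask),
    n_valid_px = sum(v),
    mean_score = mean(fm$score[v]),
    max_level = max(fm$level[v]),
    max_displacement_px = if (is.null(fm$track)) NULL else
      max(abs(fm$track$displacements)),
    warnings = warnings,
    params = c(fm$params,
               list(alpha = config$alpha, palette = config$palette,
                    display_min_level = config$display_min_level,
                    level_threshold = call$params$level_threshold,
                    min_fraction = call$params$min_fraction,
                    min_component_px = call$params$min_component_px)))

  if (!is.null(config$out_prefix)) {
    pre <- config$out_prefix
    dir.create(dirname(pre), showWarnings = FALSE, recursive = TRUE)
    write_map(fm, paste0(pre, "_score.tif"))
    lv <- fm$level
    lv[!v] <- 0L
    write_level_png(lv, paste0(pre, "_level.png"))
    write_overlay_png(
      render_overlay(fm, alpha = config$alpha,
                     display_min_level = config$display_min_level),
      paste0(pre, "_overlay.png"))
    if (!is.null(fm$track)) {
      jsonlite::write_json(list(displacements = fm$track$displacements,
                                search_radius_px = fm$track$search_radius_px,
                                subpixel = fm$track$subpixel),
                           paste0(pre, "_track.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    jsonlite::write_json(summary, paste0(pre, "_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(summary, class = "fluct_analysis", fmap = fm)
}

#' @export
print.fluct_analysis <- function(x, ...) {
  cat(sprintf("Fluctuation analysis: %s\n",
              if (x$positive) "POSITIVE (colored area present)" else "negative"))
  cat(sprintf("  colored fraction %.4f, largest component %d px, mean F %.4f, max level %d\n",
              x$colored_fraction, x$largest_component_px, x$mean_score, x$max_level))
  cat(sprintf("  %d valid of %d ROI px; motion %s\n", x$n_valid_px, x$n_roi_px,
              if (x$params$motion) sprintf("on (max |d| = %.3g px)", x$max_displacement_px)
              else "off"))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}
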