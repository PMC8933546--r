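#' Positive/negative lesion call from a fluctuation map
#'
#' The visual reading "presence of colored areas such as yellow or red in the
#' lesion" is quantified by three explicit parameters: a pixel is *colored*
#' when its level reaches `level_threshold` (default 170, the palette's
#' yellow anchor); the call is positive when the colored fraction of valid
#' lesion pixels reaches `min_fraction` AND the largest 8-connected colored
#' component reaches `min_component_px` (so a salt-and-pepper scatter of
#' isolated pixels does not count as an "area").
#'
#' Raising `level_threshold` can only shrink the colored set, so it can never
#' flip a negative call to positive.
#'
#' @param fmap a [fluctmap] object.
#' @param lesion logical matrix (lesion mask), or a [roi_mask()].
#' @param level_threshold integer 0-255 (default 170).
#' @param min_fraction minimum colored fraction of valid lesion pixels
#'   (default 0.05).
#' @param min_component_px minimum size of the largest connected colored
#'   component, in pixels (default 25).
#' @return An object of class `lesion_call` with fields `positive`,
#'   `colored_fraction`, `largest_component_px`, `n_valid_lesion_px` and
#'   `params`.
#' @export
classify_lesion <- function(fmap, lesion, level_threshold = 170L,
                            min_fraction = 0.05, min_component_px = 25L) {
  stopifnot(inherits(fmap, "fluctmap"))
  if (inherits(lesion, "roi_mask")) lesion <- lesion$mask
  if (!is.logical(lesion) || !identical(dim(lesion), dim(fmap$valid))) {
    fi_stop("'lesion' must be a logical mask matching the map")
  }
  level_threshold <- as.integer(level_threshold)
  if (level_threshold < 0L || level_threshold > 255L) {
    fi_stop("'level_threshold' must be in 0..255")
  }
  vl <- lesion & fmap$valid
  n <- sum(vl)
  if (n == 0L) fi_stop("lesion mask has no valid analysed pixels")
  colored <- vl & !is.na(fmap$level) & fmap$level >= level_threshold
  frac <- sum(colored) / n
  largest <- largest_component_px(colored)
  structure(
    list(positive = frac >= min_fraction && largest >= min_component_px,
         colored_fraction = frac, largest_component_px = largest,
         n_valid_lesion_px = n,
         params = list(level_threshold = level_threshold,
                       min_fraction = min_fraction,
                       min_component_px = as.integer(min_component_px))),
    class = "lesion_call")
}

#' @export
print.lesion_call <- function(x, ...) {
  cat(sprintf("lesion_call: %s\n", if (x$positive) "POSITIVE" else "negative"))
  cat(sprintf("  colored fraction %.4f (threshold level >= %d), largest component %d px\n",
              x$colored_fraction, x$params$level_threshold, x$largest_component_px))
  cat(sprintf("  rule: fraction >= %.3g and component >= %d px over %d valid lesion px\n",
              x$params$min_fraction, x$params$min_component_px, x$n_valid_lesion_px))
  invisible(x)
}

# Size (px) of the largest 8-connected component of a logical matrix.
largest_component_px <- function(mask) {
  w <- which(mask)
  if (!length(w)) return(0L)
  nr <- nrow(mask)
  nc <- ncol(mask)
  id <- matrix(NA_integer_, nr, nc)
  id[w] <- seq_along(w)
  ri <- ((w - 1L) %% nr) + 1L
  ci <- ((w - 1L) %/% nr) + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    rj <- ri + off[1L]
    cj <- ci + off[2L]
    ok <- rj >= 1L & rj <= nr & cj >= 1L & cj <= nc
    if (!any(ok)) next
    nb <- id[cbind(rj[ok], cj[ok])]
    has <- !is.na(nb)
    if (any(has)) {
      edges <- c(edges, rbind(id[cbind(ri[ok][has], ci[ok][has])], nb[has]))
    }
  }
  g <- igraph::make_empty_graph(n = length(w), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  max(igraph::components(g)$csize)
}

#' Cohen's kappa for a 2x2 contingency table
#'
#' Chance-corrected agreement between two binary raters (here the human video
#' reader and the software call). With cell counts `a` (both positive), `b`
#' (reference positive / test negative), `c` (reference negative / test
#' positive) and `d` (both negative), `n = a+b+c+d`:
#' observed agreement `po = (a+d)/n`, chance agreement
#' `pe = ((a+b)(a+c) + (c+d)(b+d)) / n^2`, and
#' `kappa = (po - pe) / (1 - pe)`. The standard error is the large-sample
#' (Fleiss-Cohen-Everitt) formula and the 95% CI is the Wald interval
#' `kappa +/- 1.96 * se`, truncated to \eqn{[-1, 1]}.
#'
#' @param a,b,c,d non-negative cell counts; alternatively pass a 2x2 matrix
#'   as `a`.
#' @return An object of class `kappa_result` with fields `kappa`, `se`,
#'   `ci95`, `po`, `pe` and the input `table`.
#' @export
cohen_kappa <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    if (!all(dim(a) == 2L)) fi_stop("table must be 2x2")
    b_ <- a[1L, 2L]; c_ <- a[2L, 1L]; d_ <- a[2L, 2L]; a_ <- a[1L, 1L]
    a <- a_; b <- b_; c <- c_; d <- d_
  }
  cells <- c(a, b, c, d)
  if (length(cells) != 4L || anyNA(cells) || any(cells < 0)) {
    fi_stop("need four non-negative cell counts a, b, c, d")
  }
  n <- sum(cells)
  if (n < 1) fi_stop("table is empty")
  po <- (a + d) / n
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  if (1 - pe <= .Machine$double.eps) {
    fi_stop("degenerate marginals: chance agreement is 1, kappa undefined",
            class = "fluctmap_kappa_degenerate")
  }
  kappa <- (po - pe) / (1 - pe)

  # Fleiss, Cohen & Everitt large-sample variance of kappa-hat
  p <- matrix(c(a, b, c, d), 2L, 2L, byrow = TRUE) / n
  rowm <- rowSums(p)
  colm <- colSums(p)
  A <- sum(diag(p) * (1 - (rowm + colm) * (1 - kappa))^2)
  B <- (1 - kappa)^2 * (p[1L, 2L] * (colm[1L] + rowm[2L])^2 +
                        p[2L, 1L] * (colm[2L] + rowm[1L])^2)
  C <- (kappa - pe * (1 - kappa))^2
  se <- sqrt(max(0, A + B - C)) / ((1 - pe) * sqrt(n))

  ci <- c(max(-1, kappa - 1.96 * se), min(1, kappa + 1.96 * se))
  structure(list(kappa = kappa, se = se, ci95 = ci, po = po, pe = pe,
                 table = c(a = a, b = b, c = c, d = d)),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.4f [%.4f, %.4f] (se %.4f)\n",
              x$kappa, x$ci95[1L], x$ci95[2L], x$se))
  cat(sprintf("  observed agreement po = %.4f, chance agreement pe = %.4f, n = %g\n",
              x$po, x$pe, sum(x$table)))
  invisible(x)
}
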