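# Independent brute-force oracles. These deliberately mirror the printed
# definitions with naive per-pixel loops, not the package's vectorized code
# paths.

# Pearson cross-correlation of the two frames over the (2r+1)^2 window at
# every fully supported pixel, by direct double summation.
naive_xcorr <- function(prev, curr, rad) {
  nr <- nrow(prev); nc <- ncol(prev)
  r <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (i - rad < 1 || i + rad > nr || j - rad < 1 || j + rad > nc) next
      A <- prev[(i - rad):(i + rad), (j - rad):(j + rad)]
      B <- curr[(i - rad):(i + rad), (j - rad):(j + rad)]
      da <- A - mean(A)
      db <- B - mean(B)
      num <- sum(da * db)
      den <- sqrt(sum(da^2)) * sqrt(sum(db^2))
      if (den > 1e-12) r[i, j] <- num / den
    }
  }
  r
}

# Spatio-temporal mean of clamp(r, 0, 1) over the valid samples in the
# (2*rad+1)^2 neighborhood and all frame pairs, by direct looping.
naive_coincidence <- function(r_arr, valid_arr, rad) {
  d <- dim(r_arr)
  C <- matrix(NA_real_, d[2L], d[3L])
  for (i in seq_len(d[2L])) {
    for (j in seq_len(d[3L])) {
      acc <- 0
      n <- 0
      for (t in seq_len(d[1L])) {
        for (qi in max(1, i - rad):min(d[2L], i + rad)) {
          for (qj in max(1, j - rad):min(d[3L], j + rad)) {
            if (valid_arr[t, qi, qj]) {
              acc <- acc + min(max(r_arr[t, qi, qj], 0), 1)
              n <- n + 1
            }
          }
        }
      }
      if (n > 0) C[i, j] <- acc / n
    }
  }
  C
}

# Even-odd (crossing number) point-in-polygon test, one pixel at a time.
naive_polygon_mask <- function(vertices, shape) {
  m <- matrix(FALSE, shape[1L], shape[2L])
  nv <- nrow(vertices)
  for (r in 0:(shape[1L] - 1L)) {
    for (cc in 0:(shape[2L] - 1L)) {
      inside <- FALSE
      k <- 1L
      jp <- nv
      while (k <= nv) {
        y1 <- vertices[k, 1L]; x1 <- vertices[k, 2L]
        y2 <- vertices[jp, 1L]; x2 <- vertices[jp, 2L]
        if ((y1 > r) != (y2 > r)) {
          xint <- (x2 - x1) * (r - y1) / (y2 - y1) + x1
          if (cc < xint) inside <- !inside
        }
        jp <- k
        k <- k + 1L
      }
      m[r + 1L, cc + 1L] <- inside
    }
  }
  m
}

# Build a cine whose scene is rigidly translated by disp[t, ] per frame,
# by cropping shifted windows out of a larger static base image. Returns a
# cine_loop; frame t satisfies frame_t(i + dr, j + dc) = frame_1(i, j).
translated_cine <- function(base, n, disp, frame_rate_hz = 20,
                            pixel_spacing_mm = c(0.2, 0.2)) {
  pad <- (nrow(base) - n) %/% 2L
  stopifnot(pad > max(abs(disp)))
  frames <- array(0, c(nrow(disp), n, n))
  for (t in seq_len(nrow(disp))) {
    frames[t, , ] <- base[pad + seq_len(n) - disp[t, 1L],
                          pad + seq_len(n) - disp[t, 2L]]
  }
  cine_loop(frames, frame_rate_hz, pixel_spacing_mm)
}

# A deterministic speckle-like base image.
speckle_base <- function(n, seed = 42) {
  set.seed(seed)
  matrix(runif(n * n), n, n)
}

md5_of <- function(paths) unname(tools::md5sum(paths))
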