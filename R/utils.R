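# Internal numerics and error helpers shared across the package.

# Round half away from zero (half-up for non-negative input). base::round()
# rounds half to even, which would make quantized levels depend on the parity
# of neighbouring integers; a fixed half-up rule keeps levels and overlays
# bit-reproducible across platforms.
round_half_up <- function(x) floor(x + 0.5)

# Signal an input/usage error that the CLI maps to exit code 1.
fi_stop <- function(msg, class = "fluctmap_input_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "fluctmap_error", "error", "condition")))
}

# Zero-padded integral image: P has dim (nr+1, nc+1) and
# P[i+1, j+1] = sum(m[1:i, 1:j]).
integral_image <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  p <- matrix(0, nr + 1L, nc + 1L)
  p[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  p
}

# Box sums over the (2*rad[1]+1) x (2*rad[2]+1) window centred at every pixel,
# with the window clipped at the frame border. Returns the sum matrix plus the
# mask of pixels whose window is fully supported (no clipping).
box_sum <- function(m, rad) {
  rr <- rad[1L]
  rc <- rad[2L]
  nr <- nrow(m)
  nc <- ncol(m)
  p <- integral_image(m)
  i <- seq_len(nr)
  j <- seq_len(nc)
  r1 <- pmax(i - rr, 1L)
  r2 <- pmin(i + rr, nr)
  c1 <- pmax(j - rc, 1L)
  c2 <- pmin(j + rc, nc)
  # linear indices into p (dim nr+1 x nc+1): p[a, b] -> (b-1)*(nr+1) + a
  A <- function(rowv, colv) {
    p[rep((colv - 1L) * (nr + 1L), each = nr) + rowv]
  }
  s <- A(r2 + 1L, c2 + 1L) - A(r1, c2 + 1L) - A(r2 + 1L, c1) + A(r1, c1)
  support <- outer(i - rr >= 1L & i + rr <= nr, j - rc >= 1L & j + rc <= nc, "&")
  list(sum = matrix(s, nr, nc), support = support)
}

# Number of pixels in the clipped window at each position.
box_count <- function(nr, nc, rad) {
  i <- seq_len(nr)
  j <- seq_len(nc)
  nrow_w <- pmin(i + rad[1L], nr) - pmax(i - rad[1L], 1L) + 1L
  ncol_w <- pmin(j + rad[2L], nc) - pmax(j - rad[2L], 1L) + 1L
  outer(nrow_w, ncol_w)
}

# Expand a scalar-or-length-2 radius argument to an integer pair.
as_radius_pair <- function(x, min_allowed, arg) {
  r <- as.integer(round_half_up(x))
  if (length(r) == 1L) r <- c(r, r)
  if (length(r) != 2L || anyNA(r) || any(r < min_allowed)) {
    fi_stop(sprintf("'%s' must be one or two integers >= %d", arg, min_allowed))
  }
  r
}

# Run an expression with a private RNG stream seeded by `seed`, restoring the
# caller's .Random.seed afterwards so simulation never perturbs user state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
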