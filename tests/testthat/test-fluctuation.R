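test_that("self-correlation, positive linear maps and contrast inversion hit the exact limits", {
  set.seed(21)
  f <- matrix(runif(32 * 32), 32, 32)
  same <- local_xcorr_pair(f, f, 2)
  expect_true(any(same$valid))
  expect_equal(max(abs(same$r[same$valid] - 1)), 0, tolerance = 1e-9)
  lin <- local_xcorr_pair(f, 0.4 * f + 0.1, 2)
  expect_equal(max(abs(lin$r[lin$valid] - 1)), 0, tolerance = 1e-9)
  inv <- local_xcorr_pair(f, max(f) - f, 2)
  expect_equal(max(abs(inv$r[inv$valid] + 1)), 0, tolerance = 1e-9)
})

test_that("vectorized R matches the naive double-sum formula to 1e-10", {
  set.seed(22)
  for (rep in 1:3) {
    a <- matrix(runif(32 * 32), 32, 32)
    b <- matrix(runif(32 * 32), 32, 32)
    fast <- local_xcorr_pair(a, b, 2)
    slow <- naive_xcorr(a, b, 2)
    expect_identical(fast$valid, !is.na(slow))
    expect_lt(max(abs(fast$r[fast$valid] - slow[fast$valid])), 1e-10)
  }
})

test_that("window support and zero-variance windows are marked invalid", {
  set.seed(23)
  a <- matrix(runif(20 * 20), 20, 20)
  b <- matrix(runif(20 * 20), 20, 20)
  a[1:9, 1:9] <- 0.5  # constant patch -> zero variance windows
  sl <- local_xcorr_pair(a, b, 2)
  expect_false(any(sl$valid[c(1, 2, 19, 20), ]))  # no padding at borders
  expect_false(any(sl$valid[, c(1, 2, 19, 20)]))
  expect_false(sl$valid[5, 5])
  expect_error(local_xcorr_pair(a, b, 0), "window_radius_px")
})

test_that("coincidence equals the brute-force spatio-temporal mean of clamped R", {
  set.seed(24)
  T1 <- 4
  r <- array(runif(T1 * 12 * 12, -1, 1), c(T1, 12, 12))
  valid <- array(runif(T1 * 12 * 12) > 0.25, c(T1, 12, 12))
  cm <- coincidence_map(list(r = r, valid = valid), 1)
  slow <- naive_coincidence(r, valid, 1)
  expect_identical(cm$valid, !is.na(slow))
  expect_lt(max(abs(cm$coincidence[cm$valid] - slow[cm$valid])), 1e-12)
  # all-ones and all-clamped-to-zero extremes
  ones <- coincidence_map(list(r = array(1, c(2, 8, 8)),
                               valid = array(TRUE, c(2, 8, 8))), 1)
  expect_true(all(ones$coincidence == 1))
  negs <- coincidence_map(list(r = array(-0.5, c(2, 8, 8)),
                               valid = array(TRUE, c(2, 8, 8))), 1)
  expect_true(all(negs$coincidence == 0))
})

test_that("a static cine maps to zero fluctuation and a repeated-noise cine to high fluctuation", {
  sim <- simulate_cine(synthetic_spec(shape = c(70, 48, 48), noise_sigma = 0,
                                      seed = 5))
  roi <- roi_rect(8, 8, 40, 40, c(48, 48))
  fm <- fluctmap(sim$cine, roi, motion = FALSE)
  expect_true(any(fm$valid))
  expect_true(all(fm$score[fm$valid] == 0))
  expect_true(all(fm$level[fm$valid] == 0L))
  # 70 independent noise frames, 9x9 window (radius 4 at 0.2 mm spacing)
  set.seed(26)
  noise <- array(runif(70 * 40 * 40), c(70, 40, 40))
  cine <- cine_loop(noise, 20, c(0.2, 0.2))
  roi2 <- roi_rect(6, 6, 34, 34, c(40, 40))
  fm2 <- fluctmap(cine, roi2, window_mm = 1.6, motion = FALSE)
  expect_gte(mean(fm2$score[fm2$valid]), 0.9)
})

test_that("fluctuation is invariant under positive linear intensity maps", {
  sim <- simulate_cine(synthetic_preset("flutter", seed = 9)$spec)
  roi <- roi_rect(17, 17, 47, 47, c(64, 64))
  fm1 <- fluctmap(sim$cine, roi, motion = FALSE)
  scaled <- cine_loop(0.55 * sim$cine$frames + 0.2, sim$cine$frame_rate_hz,
                      sim$cine$pixel_spacing_mm)
  fm2 <- fluctmap(scaled, roi, motion = FALSE)
  expect_identical(fm1$valid, fm2$valid)
  expect_lt(max(abs(fm1$score[fm1$valid] - fm2$score[fm2$valid])), 1e-9)
})

test_that("maps respect boundedness and internal consistency invariants", {
  for (seed in c(31, 32)) {
    ps <- synthetic_preset("both", seed = seed)
    sim <- simulate_cine(ps$spec)
    fm <- fluctmap(sim$cine, ps$roi, n_frames = 70, motion = FALSE)
    v <- fm$valid
    expect_true(all(fm$score[v] >= 0 & fm$score[v] <= 1))
    expect_true(all(fm$coincidence[v] >= 0 & fm$coincidence[v] <= 1))
    expect_true(all(fm$level[v] >= 0L & fm$level[v] <= 255L))
    expect_equal(fm$score[v] + fm$coincidence[v], rep(1, sum(v)))
    expect_identical(fm$level[v], as.integer(floor(255 * fm$score[v] + 0.5)))
  }
})

test_that("a fluttering disc stands out against far-field static speckle", {
  ps <- synthetic_preset("flutter", seed = 41)
  sim <- simulate_cine(ps$spec)
  full <- roi_rect(0, 0, 64, 64, c(64, 64))
  fm <- fluctmap(sim$cine, full, motion = FALSE)
  inside <- sim$flutter_mask & fm$valid
  outside <- !sim$flutter_mask & fm$valid
  expect_gte(mean(fm$score[inside]), 3 * mean(fm$score[outside]))
})

test_that("at rho = 1 the flutter region is indistinguishable from background", {
  diffs <- vapply(1:3, function(seed) {
    ps <- synthetic_preset("flutter", seed = 100 + seed, rho = 1.0)
    sim <- simulate_cine(ps$spec)
    full <- roi_rect(0, 0, 64, 64, c(64, 64))
    fm <- fluctmap(sim$cine, full, motion = FALSE)
    mean(fm$score[sim$flutter_mask & fm$valid]) -
      mean(fm$score[!sim$flutter_mask & fm$valid])
  }, numeric(1))
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lte(abs(mean(diffs)), 2 * se + 1e-4)
})

test_that("insufficient frames and empty ROIs raise stage errors", {
  sim <- simulate_cine(synthetic_spec(shape = c(10, 32, 32), seed = 6))
  roi <- roi_rect(8, 8, 24, 24, c(32, 32))
  expect_error(fluctmap(sim$cine, roi, n_frames = 70, motion = FALSE),
               "insufficient frames")
  edge_roi <- roi_rect(0, 0, 2, 2, c(32, 32))
  expect_error(fluctmap(sim$cine, edge_roi, n_frames = 10, motion = FALSE))
})
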