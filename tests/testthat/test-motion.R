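test_that("a static cine yields the zero track", {
  base <- speckle_base(60)
  disp <- matrix(0L, 6, 2)
  cine <- translated_cine(base, 40, disp)
  roi <- roi_rect(10, 10, 30, 30, c(40, 40))
  tr <- estimate_motion(cine, roi, search_radius_px = 5)
  expect_true(all(tr$displacements == 0))
})

test_that("constant and sinusoidal integer translations are recovered exactly", {
  base <- speckle_base(80)
  n <- 48
  roi <- roi_rect(14, 14, 34, 34, c(n, n))
  # constant (3, -2) from frame 2 on
  disp <- rbind(c(0, 0), matrix(rep(c(3, -2), each = 9), 9, 2))
  cine <- translated_cine(base, n, disp)
  tr <- estimate_motion(cine, roi, search_radius_px = 5)
  expect_identical(tr$displacements, disp * 1.0)
  # integer-rounded 2 px sinusoid at 1 Hz, 20 fps
  t <- 0:19
  disp2 <- cbind(round(2 * sin(2 * pi * t / 20)), 0)
  cine2 <- translated_cine(base, n, disp2)
  tr2 <- estimate_motion(cine2, roi, search_radius_px = 5)
  expect_identical(tr2$displacements, disp2 * 1.0)
})

test_that("compensation with a zero track is the identity", {
  base <- speckle_base(60)
  cine <- translated_cine(base, 40, matrix(0L, 4, 2))
  tr <- structure(list(displacements = matrix(0, 4, 2),
                       search_radius_px = 1L, subpixel = FALSE),
                  class = "motion_track")
  out <- compensate(cine, tr)
  expect_identical(out$frames, cine$frames)
})

test_that("compensating an estimated integer track restores frame 0 where valid", {
  base <- speckle_base(80)
  n <- 48
  disp <- rbind(c(0, 0), c(4, -3), c(-2, 5), c(1, 1))
  cine <- translated_cine(base, n, disp)
  roi <- roi_rect(14, 14, 34, 34, c(n, n))
  tr <- estimate_motion(cine, roi, search_radius_px = 6)
  out <- compensate(cine, tr)
  for (t in 2:4) {
    v <- out$valid[t, , ]
    expect_gt(mean(v), 0.7)
    expect_equal(out$frames[t, , ][v], cine$frames[1, , ][v])
  }
  # re-estimating on the compensated cine gives the zero track
  tr2 <- estimate_motion(out, roi, search_radius_px = 6)
  expect_true(all(tr2$displacements == 0))
})

test_that("bilinear compensation of a fractional ramp shift is exact in the interior", {
  n <- 32
  ramp <- outer(seq_len(n), seq_len(n), function(i, j) 0.2 + 0.01 * i + 0.005 * j)
  # scene translated by +0.5 rows: frame2(i + 0.5, j) = ramp(i, j)
  shifted <- outer(seq_len(n), seq_len(n),
                   function(i, j) 0.2 + 0.01 * (i - 0.5) + 0.005 * j)
  frames <- array(0, c(2, n, n))
  frames[1, , ] <- ramp
  frames[2, , ] <- shifted
  cine <- cine_loop(frames, 20, c(0.2, 0.2))
  tr <- structure(list(displacements = rbind(c(0, 0), c(0.5, 0)),
                       search_radius_px = 1L, subpixel = TRUE),
                  class = "motion_track")
  out <- compensate(cine, tr)
  interior <- out$valid[2, , ]
  expect_gt(sum(interior), 0.9 * n * n)
  expect_lt(max(abs((out$frames[2, , ] - ramp)[interior])), 1e-6)
})

test_that("motion preconditions are enforced", {
  base <- speckle_base(60)
  cine <- translated_cine(base, 40, matrix(0L, 3, 2))
  roi_edge <- roi_rect(0, 0, 10, 10, c(40, 40))
  expect_error(estimate_motion(cine, roi_edge, search_radius_px = 5),
               "does not fit")
  flat <- cine_loop(array(0.5, c(3, 40, 40)), 20, c(0.2, 0.2))
  roi <- roi_rect(10, 10, 30, 30, c(40, 40))
  expect_error(estimate_motion(flat, roi, 5), "zero intensity variance")
  tr_short <- structure(list(displacements = matrix(0, 2, 2),
                             search_radius_px = 1L, subpixel = FALSE),
                        class = "motion_track")
  expect_error(compensate(cine, tr_short), "track length")
  tr_big <- structure(list(displacements = rbind(c(0, 0), c(50, 0), c(0, 0)),
                           search_radius_px = 60L, subpixel = FALSE),
                      class = "motion_track")
  expect_error(compensate(cine, tr_big), "exceeds frame size")
})
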