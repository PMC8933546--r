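# Minimal hand-built map object for classifier unit tests.
fake_map <- function(level, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(level), ncol(level))
  structure(list(score = level / 255, level = level, valid = valid),
            class = "fluctmap")
}

test_that("all-zero and all-saturated level maps give the trivial calls", {
  lesion <- matrix(TRUE, 20, 20)
  zero <- classify_lesion(fake_map(matrix(0L, 20, 20)), lesion)
  expect_false(zero$positive)
  expect_equal(zero$colored_fraction, 0)
  sat <- classify_lesion(fake_map(matrix(255L, 20, 20)), lesion)
  expect_true(sat$positive)
  expect_equal(sat$colored_fraction, 1)
  expect_equal(sat$largest_component_px, 400)
})

test_that("the component rule rejects scattered pixels but accepts a blob", {
  lesion <- matrix(TRUE, 20, 20)
  lv <- matrix(0L, 20, 20)
  lv[cbind(seq(1, 19, 3), seq(1, 19, 3))] <- 255L  # isolated pixels, ~7/400
  scattered <- classify_lesion(fake_map(lv), lesion, min_fraction = 0.01)
  expect_false(scattered$positive)
  expect_equal(scattered$largest_component_px, 1)
  lv2 <- matrix(0L, 20, 20)
  lv2[5:10, 5:10] <- 255L  # 36 px, 8-connected
  blob <- classify_lesion(fake_map(lv2), lesion)
  expect_true(blob$positive)
  expect_equal(blob$largest_component_px, 36)
})

test_that("diagonal touching counts as one component (8-connectivity)", {
  lesion <- matrix(TRUE, 10, 10)
  lv <- matrix(0L, 10, 10)
  lv[cbind(1:6, 1:6)] <- 255L  # a diagonal line
  call <- classify_lesion(fake_map(lv), lesion, min_fraction = 0.01,
                          min_component_px = 6)
  expect_equal(call$largest_component_px, 6)
  expect_true(call$positive)
})

test_that("raising the level threshold never flips a negative call to positive", {
  set.seed(61)
  for (rep in 1:5) {
    lv <- matrix(sample(0:255, 400, TRUE), 20, 20)
    lesion <- matrix(runif(400) > 0.3, 20, 20)
    prev_positive <- TRUE
    for (thr in c(0, 64, 128, 170, 220, 255)) {
      call <- classify_lesion(fake_map(lv), lesion, level_threshold = thr,
                              min_fraction = 0.05, min_component_px = 4)
      expect_false(!prev_positive && call$positive)
      prev_positive <- call$positive
    }
  }
})

test_that("lesions with no valid analysed pixels are an error", {
  fm <- fake_map(matrix(0L, 8, 8), valid = matrix(FALSE, 8, 8))
  expect_error(classify_lesion(fm, matrix(TRUE, 8, 8)), "no valid")
})

test_that("Cohen's kappa reproduces hand-derived closed-form values", {
  perfect <- cohen_kappa(31, 0, 0, 31)
  expect_identical(perfect$kappa, 1)
  expect_identical(perfect$se, 0)
  chance <- cohen_kappa(25, 25, 25, 25)
  expect_identical(chance$kappa, 0)
  expect_equal(chance$se, 0.1, tolerance = 1e-12)
  # po = 62/66, pe = 2188/4356 by hand
  t1 <- cohen_kappa(34, 4, 0, 28)
  expect_equal(t1$po, 62 / 66, tolerance = 1e-12)
  expect_equal(t1$pe, 2188 / 4356, tolerance = 1e-12)
  expect_equal(t1$kappa, (62 / 66 - 2188 / 4356) / (1 - 2188 / 4356),
               tolerance = 1e-12)
  expect_equal(t1$kappa, 0.8782, tolerance = 1e-4)
  # frozen independent oracle (statsmodels cohens_kappa) for the SE
  expect_equal(t1$se, 0.0585726010, tolerance = 1e-8)
  expect_equal(t1$ci95, t1$kappa + c(-1.96, 1.96) * t1$se, tolerance = 1e-12)
})

test_that("kappa is symmetric in the raters and scale-invariant in the counts", {
  set.seed(62)
  for (rep in 1:10) {
    cells <- sample(0:40, 4, TRUE)
    if (sum(cells) == 0) cells <- cells + 1
    k1 <- try(cohen_kappa(cells[1], cells[2], cells[3], cells[4]), silent = TRUE)
    k2 <- try(cohen_kappa(cells[1], cells[3], cells[2], cells[4]), silent = TRUE)
    if (inherits(k1, "try-error")) {
      expect_true(inherits(k2, "try-error"))
      next
    }
    expect_equal(k1$kappa, k2$kappa, tolerance = 1e-12)
    k3 <- cohen_kappa(5 * cells[1], 5 * cells[2], 5 * cells[3], 5 * cells[4])
    expect_equal(k1$kappa, k3$kappa, tolerance = 1e-12)
    expect_true(k1$kappa >= -1 && k1$kappa <= 1)
    expect_true(k1$ci95[1] <= k1$kappa && k1$kappa <= k1$ci95[2])
  }
})

test_that("degenerate marginals are signalled, not silently NaN", {
  expect_error(cohen_kappa(10, 0, 0, 0), class = "fluctmap_kappa_degenerate")
  expect_error(cohen_kappa(0, 0, 0, 0), "empty")
})
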