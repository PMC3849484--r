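test_that("uniform images segment entirely in or entirely out", {
  img <- uniformImage(6, 9, c(100, 60, 40))
  rg <- colorRange(r = c(90, 110), g = c(50, 70), b = c(30, 50))
  m <- segmentByColor(img, rg)
  expect_true(all(m))
  expect_equal(sum(m), 54)

  white <- uniformImage(6, 9, c(255, 255, 255))
  expect_false(any(segmentByColor(white, defaultCfg@ranges$darkest)))
})

test_that("segmentation matches the per-pixel brute-force oracle", {
  set.seed(11)
  for (k in 1:25) {
    img <- randomImage(8, 8)
    lo <- sample(0:200, 3); hi <- lo + sample(0:55, 3)
    rg <- colorRange(r = c(lo[1], hi[1]), g = c(lo[2], hi[2]),
                     b = c(lo[3], hi[3]))
    expect_identical(segmentByColor(img, rg), bruteSegment(img, lo, hi))
  }
})

test_that("widening a color range never shrinks the segmented area", {
  set.seed(13)
  for (k in 1:10) {
    img <- randomImage(12, 12)
    lo <- sample(30:120, 3); hi <- lo + sample(10:60, 3)
    narrow <- colorRange(r = c(lo[1], hi[1]), g = c(lo[2], hi[2]),
                         b = c(lo[3], hi[3]))
    wlo <- pmax(0, lo - sample(0:30, 3)); whi <- pmin(255, hi + sample(0:30, 3))
    wide <- colorRange(r = c(wlo[1], whi[1]), g = c(wlo[2], whi[2]),
                       b = c(wlo[3], whi[3]))
    expect_gte(sum(segmentByColor(img, wide)), sum(segmentByColor(img, narrow)))
  }
})

test_that("color ranges with lo > hi cannot be constructed", {
  expect_error(colorRange(r = c(140, 60), g = c(20, 90), b = c(0, 70)),
               "lo <= hi")
})

test_that("sentinel masking replaces exactly the masked pixels", {
  set.seed(3)
  img <- randomImage(7, 7)
  none <- matrix(FALSE, 7, 7)
  expect_identical(applySentinelMask(img, none, c(0, 255, 0)), img)

  all <- matrix(TRUE, 7, 7)
  out <- applySentinelMask(img, all, c(0, 255, 0))
  expect_true(all(out[, , 1] == 0 & out[, , 2] == 255 & out[, , 3] == 0))

  m <- matrix(FALSE, 7, 7); m[2:3, 4:6] <- TRUE
  once <- applySentinelMask(img, m, c(0, 255, 0))
  twice <- applySentinelMask(once, m, c(0, 255, 0))
  expect_identical(once, twice)          # idempotent
  expect_identical(img[1, 1, ], once[1, 1, ])  # untouched pixel
  expect_error(applySentinelMask(img, matrix(FALSE, 3, 3), c(0, 255, 0)),
               "dimensions")
})

test_that("after sentinel masking, masked pixels never re-segment", {
  set.seed(5)
  cfg <- defaultCfg
  for (k in 1:5) {
    img <- randomImage(10, 10)
    m <- matrix(runif(100) < 0.4, 10, 10)
    out <- applySentinelMask(img, m, cfg@sentinelColor)
    for (nm in c("darkest", "mid", "light", "widePositive")) {
      expect_false(any(segmentByColor(out, cfg@ranges[[nm]]) & m))
    }
  }
})

test_that("mask union is the pixelwise OR with the expected area bound", {
  set.seed(21)
  a <- matrix(runif(64) < 0.3, 8, 8)
  b <- matrix(runif(64) < 0.3, 8, 8)
  u <- maskUnion(list(a, b))
  expect_identical(u, a | b)
  expect_lte(sum(u), sum(a) + sum(b))
  expect_identical(maskUnion(list(a, a)), a)

  d1 <- matrix(FALSE, 4, 4); d1[1, 1] <- TRUE
  d2 <- matrix(FALSE, 4, 4); d2[4, 4] <- TRUE
  expect_equal(sum(maskUnion(list(d1, d2))), 2)  # disjoint: equality

  expect_error(maskUnion(list()), "non-empty")
  expect_error(maskUnion(list(a, matrix(FALSE, 3, 3))), "identical dimensions")
})
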