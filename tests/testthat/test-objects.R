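test_that("labeling handles empty, single-pixel and diagonal cases", {
  img <- uniformImage(5, 5, c(100, 100, 100))
  expect_equal(nObjects(labelObjects(matrix(FALSE, 5, 5), img)), 0)

  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  om <- labelObjects(m, img)
  expect_equal(nObjects(om), 1)
  expect_equal(objectFeatures(om)$area, 1)
  expect_equal(objectFeatures(om)$roundness, 1)  # degenerate convention

  m2 <- matrix(FALSE, 5, 5); m2[2, 2] <- TRUE; m2[3, 3] <- TRUE
  expect_equal(nObjects(labelObjects(m2, img)), 1)  # 8-connectivity
})

test_that("labeling agrees with a flood-fill oracle on random masks", {
  set.seed(17)
  for (k in 1:10) {
    m <- matrix(runif(15 * 15) < 0.35, 15, 15)
    img <- randomImage(15, 15)
    om <- labelObjects(m, img)
    oracle <- floodComponents(m)
    expect_equal(nObjects(om), length(oracle))
    got <- lapply(objectPixels(om), sort)
    # compare as sets of pixel sets
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(oracle, paste, "", collapse = ","))
  }
})

test_that("labels follow row-major scan order of first pixels", {
  m <- matrix(FALSE, 10, 10)
  m[6:8, 2:4] <- TRUE   # lower-left blob
  m[2:3, 7:8] <- TRUE   # upper-right blob: first in row-major order
  om <- labelObjects(m, uniformImage(10, 10, c(0, 0, 0)))
  f <- objectFeatures(om)
  expect_equal(nObjects(om), 2)
  expect_lt(f$centroidRow[1], f$centroidRow[2])
})

test_that("object areas sum to the mask area and centroids translate", {
  set.seed(23)
  m <- randomBlobMask(30, 30)
  img <- uniformImage(30, 30, c(50, 50, 50))
  om <- labelObjects(m, img)
  expect_equal(sum(objectFeatures(om)$area), sum(m))

  shifted <- matrix(FALSE, 40, 40)
  shifted[6:35, 9:38] <- m
  om2 <- labelObjects(shifted, uniformImage(40, 40, c(50, 50, 50)))
  f1 <- objectFeatures(om); f2 <- objectFeatures(om2)
  expect_equal(f2$centroidRow, f1$centroidRow + 5)
  expect_equal(f2$centroidCol, f1$centroidCol + 8)
  expect_equal(f2$roundness, f1$roundness)
})

test_that("roundness matches the contour-step formula on known shapes", {
  # 1 x 50 line: boundary trace is 49 steps out and 49 back
  line <- matrix(FALSE, 5, 60); line[3, 5:54] <- TRUE
  expect_equal(computeRoundness(line), 98^2 / (4 * pi * 50))
  expect_gt(computeRoundness(line), 5)

  disc <- discMask(51, 51, 26, 26, 20)
  r <- computeRoundness(disc)
  expect_gte(r, 1.00)
  expect_lte(r, 1.15)

  single <- matrix(FALSE, 3, 3); single[2, 2] <- TRUE
  expect_equal(computeRoundness(single), 1)

  expect_error(computeRoundness(matrix(FALSE, 3, 3)), "non-empty")
  two <- matrix(FALSE, 5, 5); two[1, 1] <- TRUE; two[5, 5] <- TRUE
  expect_error(computeRoundness(two), "exactly one")
})

test_that("morphology filters cannot be constructed inverted", {
  expect_error(morphFilter(area = c(10, 5)), "areaMin")
  expect_error(morphFilter(roundness = c(0.5, 2)), "roundnessMin")
  expect_error(morphFilter(roundness = c(3, 2)), "roundnessMin")
})

test_that("filterObjects matches the brute-force per-object predicate", {
  set.seed(29)
  for (k in 1:8) {
    m <- randomBlobMask(40, 40, nBlobs = 8)
    img <- randomImage(40, 40)
    om <- labelObjects(m, img)
    aBounds <- sort(sample(1:120, 2))
    rBounds <- 1 + sort(runif(2, 0, 1.5))
    flt <- morphFilter(area = aBounds, roundness = rBounds)
    kept <- filterObjects(om, flt)

    # oracle: recompute each object's area and roundness from its own pixels
    H <- nrow(m)
    keepOracle <- vapply(objectPixels(om), function(px) {
      sub <- matrix(FALSE, 40, 40); sub[px] <- TRUE
      a <- length(px); r <- computeRoundness(sub)
      a >= aBounds[1] && a <= aBounds[2] && r >= rBounds[1] && r <= rBounds[2]
    }, logical(1))
    expect_equal(nObjects(kept), sum(keepOracle))
    expect_setequal(
      vapply(objectPixels(kept), paste, "", collapse = ","),
      vapply(objectPixels(om)[keepOracle], paste, "", collapse = ","))

    # idempotence and the identity filter
    expect_identical(filterObjects(kept, flt), kept)
    ident <- morphFilter()
    expect_identical(filterObjects(om, ident), om)
  }
})

test_that("filtered maps keep contiguous labels and a consistent mask", {
  set.seed(31)
  m <- randomBlobMask(30, 30, nBlobs = 6)
  om <- labelObjects(m, uniformImage(30, 30, c(10, 10, 10)))
  kept <- filterObjects(om, morphFilter(area = c(5, 60)))
  f <- objectFeatures(kept)
  expect_identical(f$label, seq_len(nrow(f)))
  expect_equal(sum(objectMask(kept)), sum(f$area))
})

test_that("hole filling and border exclusion flags behave as documented", {
  ring <- discMask(21, 21, 11, 11, 8) & !discMask(21, 21, 11, 11, 4)
  img <- uniformImage(21, 21, c(0, 0, 0))
  noFill <- labelObjects(ring, img)
  fill <- labelObjects(ring, img, fillHoles = TRUE)
  expect_equal(sum(objectFeatures(fill)$area),
               sum(discMask(21, 21, 11, 11, 8)))
  expect_lt(sum(objectFeatures(noFill)$area), sum(objectFeatures(fill)$area))

  m <- matrix(FALSE, 10, 10)
  m[1, 1:3] <- TRUE        # touches border
  m[5:6, 5:6] <- TRUE      # interior
  expect_equal(nObjects(labelObjects(m, uniformImage(10, 10, c(0, 0, 0)))), 2)
  expect_equal(nObjects(labelObjects(m, uniformImage(10, 10, c(0, 0, 0)),
                                     excludeBorder = TRUE)), 1)
})
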