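test_that("scenes are bit-reproducible from their seed", {
  a <- generateScene(nPositive = 15, nNegative = 8, backgroundLevel = "low",
                     overlapFraction = 0.2, seed = 31)
  b <- generateScene(nPositive = 15, nNegative = 8, backgroundLevel = "low",
                     overlapFraction = 0.2, seed = 31)
  expect_identical(sceneImage(a), sceneImage(b))
  expect_identical(sceneNuclei(a), sceneNuclei(b))
  expect_identical(backgroundPixels(a), backgroundPixels(b))

  c2 <- generateScene(nPositive = 15, nNegative = 8, backgroundLevel = "low",
                      overlapFraction = 0.2, seed = 32)
  expect_false(identical(sceneImage(a), sceneImage(c2)))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(99)
  x1 <- runif(3)
  set.seed(99)
  invisible(generateScene(nPositive = 5, seed = 1))
  x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("ground truth bookkeeping matches the requested counts", {
  scn <- generateScene(nPositive = 37, nNegative = 5, seed = 3)
  expect_equal(sceneGroundTruth(scn), 37)

  negOnly <- generateScene(nPositive = 0, nNegative = 12, seed = 3)
  expect_equal(sceneGroundTruth(negOnly), 0)

  tot <- 0
  for (s in 1:4) {
    n <- 5 * s
    tot <- tot + sceneGroundTruth(generateScene(nPositive = n, seed = s))
  }
  expect_equal(tot, sum(5 * (1:4)))
})

test_that("an empty clean scene yields zero objects through the pipeline", {
  scn <- generateScene(nPositive = 0, nNegative = 0, seed = 1)
  res <- analyzeImage(scn)
  expect_equal(backgroundClass(res), "NONE")
  expect_equal(nObjects(res), 0)
  expect_equal(estimatedNuclei(countNuclei(selectedObjects(res))), 0)
})

test_that("nucleus palettes are contained in their segmentation ranges", {
  cfg <- defaultCfg
  scn <- generateScene(nPositive = 40, nNegative = 20, seed = 6)
  nuc <- sceneNuclei(scn)
  img <- sceneImage(scn)
  rangeFor <- c(POS_DARK = "darkest", POS_MID = "mid", POS_LIGHT = "light",
                NEG = "negative")
  for (i in seq_len(nrow(nuc))) {
    rg <- cfg@ranges[[rangeFor[[nuc$class[i]]]]]
    col <- c(nuc$colR[i], nuc$colG[i], nuc$colB[i])
    expect_true(all(col >= rangeLo(rg) & col <= rangeHi(rg)))
    # the rendered center pixel carries exactly that flat color
    px <- img[round(nuc$centerRow[i]), round(nuc$centerCol[i]), ]
    expect_equal(as.integer(px), col)
  }
})

test_that("clean scenes contain no diffuse-background indicator pixels", {
  cfg <- defaultCfg
  scn <- generateScene(nPositive = 30, nNegative = 15, seed = 10)
  img <- sceneImage(scn)
  expect_false(any(backgroundPixels(scn)))
  indicator <- segmentByColor(img, cfg@ranges$bg2) &
               !segmentByColor(img, cfg@ranges$bg1)
  expect_equal(sum(indicator), 0)
})

test_that("measured background area2 rises with the background level", {
  means <- vapply(c("none", "low", "high"), function(lev) {
    a2 <- vapply(1:5, function(s) {
      scn <- generateScene(nPositive = 20, nNegative = 10,
                           backgroundLevel = lev, seed = s)
      res <- analyzeImage(scn)
      unname(backgroundAreas(res)[2])
    }, numeric(1))
    mean(a2)
  }, numeric(1))
  expect_true(means[1] < means[2] && means[2] < means[3])
  expect_equal(unname(means[1]), 0)
})

test_that("impossible requests fail loudly", {
  expect_error(generateScene(nPositive = 5, width = 32, height = 32),
               "width")
  expect_error(generateScene(nPositive = 500, nNegative = 0,
                             width = 64, height = 64, seed = 1),
               "packing")
})

test_that("simulateScenes writes images plus a ground-truth table", {
  dir <- withr::local_tempdir()
  gt <- simulateScenes(2, dir, backgroundLevel = "none", nPositive = 8,
                       nNegative = 4, width = 256, height = 192, seed = 5)
  expect_true(file.exists(file.path(dir, "scene_001.png")))
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  tab <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$n_positive, c(8, 8))
  img <- readRGBImage(file.path(dir, "scene_001.png"))
  expect_identical(img,
                   sceneImage(generateScene(8, 4, "none", 0.15, 256, 192, 5)))
})
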