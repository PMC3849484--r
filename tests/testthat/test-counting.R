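# ObjectMap with rectangles of chosen sizes (rect roundness stays <= 1.3
# for near-square aspect, > 1.3 for elongated ones)
rectMap <- function(sizes, gap = 5) {
  H <- max(vapply(sizes, `[`, 0, 1)) + 10
  W <- sum(vapply(sizes, `[`, 0, 2)) + gap * (length(sizes) + 1)
  m <- matrix(FALSE, H, W)
  x <- gap
  for (s in sizes) {
    m[3:(2 + s[1]), x:(x + s[2] - 1)] <- TRUE
    x <- x + s[2] + gap
  }
  labelObjects(m, uniformImage(H, W, c(0, 0, 0)))
}

test_that("mean nucleus area: passthrough, median of round objects, fallback", {
  cfg <- defaultCfg
  cfgFixed <- cfg; cfgFixed@meanNucleusArea <- 400
  om <- rectMap(list(c(15, 20), c(20, 20), c(20, 25)))  # areas 300, 400, 500
  expect_equal(estimateMeanNucleusArea(om, cfgFixed), 400)

  expect_true(all(objectFeatures(om)$roundness <= 1.3))
  expect_equal(estimateMeanNucleusArea(om, cfg), 400)  # median

  elongated <- rectMap(list(c(4, 60), c(3, 80)))  # roundness > 1.3
  expect_true(all(objectFeatures(elongated)$roundness > 1.3))
  expect_equal(estimateMeanNucleusArea(elongated, cfg), 450)  # fallback
})

test_that("cluster splitting follows the area-quotient rule", {
  cfg <- defaultCfg
  # one object at exactly the mean area -> a singleton
  om1 <- rectMap(list(c(20, 20)))
  r1 <- countNuclei(om1, meanArea = 400, cfg = cfg)
  expect_equal(estimatedNuclei(r1), 1)
  expect_equal(r1@nSingletons, 1)

  # 3.4x the mean area -> cluster contributing round(3.4) = 3
  om2 <- rectMap(list(c(34, 40)))  # 1360 px^2
  r2 <- countNuclei(om2, meanArea = 400, cfg = cfg)
  expect_equal(r2@nClusters, 1)
  expect_equal(estimatedNuclei(r2), 3)

  # half-way quotients round away from zero: 2.5 -> 3
  om3 <- rectMap(list(c(25, 40)))  # 1000 px^2
  expect_equal(estimatedNuclei(countNuclei(om3, meanArea = 400, cfg = cfg)), 3)

  # a cluster barely above the threshold still counts at least 2
  om4 <- rectMap(list(c(20, 31)))  # 620 px^2 = 1.55 x mean
  r4 <- countNuclei(om4, meanArea = 400, cfg = cfg)
  expect_equal(r4@nClusters, 1)
  expect_equal(estimatedNuclei(r4), 2)

  expect_error(countNuclei(om1, meanArea = 0), "positive")
  expect_error(countNuclei(om1, meanArea = -5), "positive")
})

test_that("estimated count is monotone in object area", {
  cfg <- defaultCfg
  sizes <- list(c(20, 20), c(20, 30), c(20, 45))
  ests <- vapply(seq_along(sizes), function(k) {
    om <- rectMap(sizes[seq_len(k)])
    estimatedNuclei(countNuclei(om, meanArea = 400, cfg = cfg))
  }, numeric(1))
  expect_true(all(diff(ests) > 0))

  # doubling every area never lowers the estimate
  omA <- rectMap(list(c(20, 20), c(20, 30)))
  omB <- rectMap(list(c(20, 40), c(40, 30)))
  expect_gte(estimatedNuclei(countNuclei(omB, meanArea = 400, cfg = cfg)),
             estimatedNuclei(countNuclei(omA, meanArea = 400, cfg = cfg)))
})

test_that("well-separated synthetic nuclei are counted exactly", {
  cfg <- defaultCfg
  scn <- generateScene(nPositive = 12, nNegative = 6, seed = 2)
  res <- analyzeImage(scn, cfg)
  cnt <- countNuclei(selectedObjects(res), cfg = cfg)
  expect_equal(estimatedNuclei(cnt), 12)
  expect_gte(estimatedNuclei(cnt), nObjects(cnt))
})

test_that("complexity grouping splits at the cutoff", {
  expect_equal(classifyComplexity(100), "LOW")
  expect_equal(classifyComplexity(101), "HIGH")
  expect_equal(classifyComplexity(0), "LOW")
  expect_equal(classifyComplexity(c(5, 150), cutoff = 100), c("LOW", "HIGH"))
  expect_equal(classifyComplexity(30, cutoff = 20), "HIGH")
})
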