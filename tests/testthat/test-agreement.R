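test_that("identical pairs give zero bias and degenerate limits", {
  p <- pairedCounts(1:3, c(10, 25, 90), c(10, 25, 90))
  s <- blandAltman(p)
  expect_equal(meanDifference(s), 0)
  expect_equal(s@sdDiff, 0)
  expect_equal(unname(limitsOfAgreement(s)), c(0, 0))
})

test_that("the three-pair worked example reproduces the closed form", {
  p <- pairedCounts(1:3, c(10, 20, 30), c(12, 18, 33))
  s <- blandAltman(p)
  # diffs {-2, 2, -3}: mean -1, sample SD sqrt(7)
  expect_equal(meanDifference(s), -1, tolerance = 1e-12)
  expect_equal(s@sdDiff, sqrt(7), tolerance = 1e-12)
  expect_equal(unname(limitsOfAgreement(s)),
               c(-1 - 1.96 * sqrt(7), -1 + 1.96 * sqrt(7)), tolerance = 1e-12)
  pts <- agreementPoints(s)
  expect_equal(pts$pairMean, c(11, 19, 31.5))
  expect_equal(pts$diff, c(-2, 2, -3))
})

test_that("agreement analysis rejects degenerate input", {
  expect_error(blandAltman(pairedCounts("a", 5, 7)), "at least 2")
  expect_error(pairedCounts(c("a", "a"), c(1, 2), c(1, 2)), "unique")
  expect_error(pairedCounts("a", -1, 2), ">= 0")
})

test_that("swapping the methods negates the bias and mirrors the limits", {
  set.seed(8)
  p <- pairedCounts(1:20, rpois(20, 60), rpois(20, 55))
  q <- pairedCounts(p$imageId, p$countB, p$countA)
  s1 <- blandAltman(p); s2 <- blandAltman(q)
  expect_equal(meanDifference(s2), -meanDifference(s1))
  expect_equal(unname(limitsOfAgreement(s2)),
               -rev(unname(limitsOfAgreement(s1))))
})

test_that("the difference curve is the empirical survival of |diff|", {
  p <- pairedCounts(1:4, c(10, 20, 80, 100), c(10, 30, 30, 40))  # |d| 0,10,50,60
  crv <- differenceCurve(p)
  expect_equal(probabilityAtLeast(crv, 50), 0.5)
  expect_equal(probabilityAtLeast(crv, 0), 1)
  expect_equal(probabilityAtLeast(crv, 61), 0)
  pts <- curvePoints(crv)
  expect_equal(pts$d[1], 0)
  expect_equal(pts$prob[1], 1)
  expect_true(all(diff(pts$prob) <= 0))

  allZero <- differenceCurve(pairedCounts(1:3, c(4, 5, 6), c(4, 5, 6)))
  expect_equal(probabilityAtLeast(allZero, c(1, 10, 100)), c(0, 0, 0))

  one <- differenceCurve(pairedCounts("x", 10, 3))
  expect_equal(probabilityAtLeast(one, 7), 1)
  expect_equal(probabilityAtLeast(one, 8), 0)
})

test_that("stratified comparison mirrors per-subset analyses", {
  set.seed(15)
  n <- 30
  p <- pairedCounts(1:n, rpois(n, 80), rpois(n, 75),
                    stratum = sample(c("bg", "clean"), n, TRUE))
  out <- stratifiedCompare(p)
  expect_setequal(names(out), unique(p$stratum))
  expect_equal(sum(vapply(out, `[[`, 0, "n")), n)
  for (g in names(out)) {
    sub <- p[p$stratum == g, ]
    expect_equal(curvePoints(out[[g]]$curve), curvePoints(differenceCurve(sub)))
    expect_equal(meanDifference(out[[g]]$blandAltman),
                 meanDifference(blandAltman(sub)))
  }

  # two strata with identical data give identical summaries
  dup <- rbind(
    pairedCounts(paste0("a", 1:3), c(10, 20, 30), c(12, 18, 33), "s1"),
    pairedCounts(paste0("b", 1:3), c(10, 20, 30), c(12, 18, 33), "s2"))
  res <- stratifiedCompare(dup)
  expect_equal(meanDifference(res$s1$blandAltman),
               meanDifference(res$s2$blandAltman))
  expect_equal(curvePoints(res$s1$curve), curvePoints(res$s2$curve))

  # a singleton stratum is flagged and keeps its curve
  tiny <- pairedCounts(1:3, c(5, 6, 7), c(5, 9, 7), c("x", "y", "y"))
  res2 <- stratifiedCompare(tiny)
  expect_true(res2$x$flagged)
  expect_null(res2$x$blandAltman)
  expect_s4_class(res2$x$curve, "DifferenceCurve")

  expect_error(stratifiedCompare(p, by = "nope"), "unknown grouping")
})
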