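#' @rdname ihcquant-accessors
setMethod("rangeLo", "ColorRange", function(x) x@lo)
#' @rdname ihcquant-accessors
setMethod("rangeHi", "ColorRange", function(x) x@hi)

#' @rdname ihcquant-accessors
setMethod("objectMask", "ObjectMap", function(x) x@mask)
#' @rdname ihcquant-accessors
setMethod("objectFeatures", "ObjectMap", function(x) x@features)
#' @rdname ihcquant-accessors
setMethod("objectPixels", "ObjectMap", function(x) x@pixels)
#' @rdname ihcquant-accessors
setMethod("nObjects", "ObjectMap", function(x) length(x@pixels))
#' @rdname ihcquant-accessors
setMethod("stepTag", "ObjectMap", function(x) x@stepTag)

#' @rdname ihcquant-accessors
setMethod("macroUsed", "MacroResult", function(x) x@macroUsed)
#' @rdname ihcquant-accessors
setMethod("selectedObjects", "MacroResult", function(x) x@selected)
#' @rdname ihcquant-accessors
setMethod("stepMaps", "MacroResult", function(x) x@stepMaps)
#' @rdname ihcquant-accessors
setMethod("backgroundAssessment", "MacroResult", function(x) x@assessment)
#' @rdname ihcquant-accessors
setMethod("nObjects", "MacroResult", function(x) length(x@selected@pixels))

#' @rdname ihcquant-accessors
setMethod("backgroundClass", "BackgroundAssessment",
          function(x) x@backgroundClass)
#' @rdname ihcquant-accessors
setMethod("backgroundClass", "MacroResult",
          function(x) x@assessment@backgroundClass)
#' @rdname ihcquant-accessors
setMethod("backgroundAreas", "BackgroundAssessment",
          function(x) c(area1 = x@area1, area2 = x@area2))
#' @rdname ihcquant-accessors
setMethod("backgroundAreas", "MacroResult",
          function(x) backgroundAreas(x@assessment))
#' @rdname ihcquant-accessors
setMethod("backgroundRatio", "BackgroundAssessment", function(x) x@ratio)
#' @rdname ihcquant-accessors
setMethod("backgroundRatio", "MacroResult", function(x) x@assessment@ratio)

#' @rdname ihcquant-accessors
setMethod("nObjects", "CountResult", function(x) x@nObjects)
#' @rdname ihcquant-accessors
setMethod("estimatedNuclei", "CountResult", function(x) x@estimatedNuclei)
#' @rdname ihcquant-accessors
setMethod("imageComplexity", "CountResult", function(x) x@complexity)

#' @rdname ihcquant-accessors
setMethod("sceneImage", "SyntheticScene", function(x) x@image)
#' @rdname ihcquant-accessors
setMethod("sceneNuclei", "SyntheticScene", function(x) x@nuclei)
#' @rdname ihcquant-accessors
setMethod("backgroundLevel", "SyntheticScene", function(x) x@backgroundLevel)
#' @rdname ihcquant-accessors
setMethod("backgroundPixels", "SyntheticScene", function(x) x@backgroundPixels)

#' @rdname ihcquant-accessors
setMethod("meanDifference", "AgreementSummary", function(x) x@meanDiff)
#' @rdname ihcquant-accessors
setMethod("limitsOfAgreement", "AgreementSummary",
          function(x) c(low = x@loaLow, high = x@loaHigh))
#' @rdname ihcquant-accessors
setMethod("agreementPoints", "AgreementSummary", function(x) x@points)

#' @rdname ihcquant-accessors
setMethod("curvePoints", "DifferenceCurve", function(x) x@curve)
#' @rdname ihcquant-accessors
setMethod("probabilityAtLeast", "DifferenceCurve", function(x, d) {
  vapply(d, function(t) mean(x@absDiffs >= t), numeric(1))
})

setMethod("show", "ColorRange", function(object) {
  cat(sprintf("ColorRange R[%d,%d] G[%d,%d] B[%d,%d]\n",
              object@lo[1], object@hi[1], object@lo[2], object@hi[2],
              object@lo[3], object@hi[3]))
})

setMethod("show", "MorphFilter", function(object) {
  cat(sprintf("MorphFilter area [%g, %g] px^2, roundness [%g, %g]\n",
              object@areaMin, object@areaMax,
              object@roundnessMin, object@roundnessMax))
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig\n  color ranges:\n")
  for (nm in .RANGE_NAMES) {
    rg <- object@ranges[[nm]]
    cat(sprintf("    %-12s R[%d,%d] G[%d,%d] B[%d,%d]\n", nm,
                rg@lo[1], rg@hi[1], rg@lo[2], rg@hi[2], rg@lo[3], rg@hi[3]))
  }
  cat("  filters:\n")
  for (nm in .FILTER_NAMES) {
    f <- object@filters[[nm]]
    cat(sprintf("    %-6s area [%g, %g], roundness [%g, %g]\n", nm,
                f@areaMin, f@areaMax, f@roundnessMin, f@roundnessMax))
  }
  cat(sprintf("  ratioThreshold: %g | sentinel: (%d,%d,%d) | meanNucleusArea: %s\n",
              object@ratioThreshold, object@sentinelColor[1],
              object@sentinelColor[2], object@sentinelColor[3],
              if (is.na(object@meanNucleusArea)) "auto"
              else format(object@meanNucleusArea)))
  cat(sprintf("  clusterFactor: %g | complexityCutoff: %d | fillHoles: %s | excludeBorder: %s\n",
              object@clusterFactor, object@complexityCutoff,
              object@fillHoles, object@excludeBorder))
})

setMethod("show", "ObjectMap", function(object) {
  cat(sprintf("ObjectMap [%s] %d x %d px, %d object(s), %d selected px\n",
              object@stepTag, nrow(object@mask), ncol(object@mask),
              length(object@pixels), sum(object@mask)))
})

setMethod("show", "BackgroundAssessment", function(object) {
  cat(sprintf("BackgroundAssessment: area1 = %g, area2 = %g, ratio = %g -> %s\n",
              object@area1, object@area2, object@ratio,
              object@backgroundClass))
})

setMethod("show", "MacroResult", function(object) {
  cat(sprintf("MacroResult: macro %s (background %s), %d selected object(s)\n",
              object@macroUsed, object@assessment@backgroundClass,
              length(object@selected@pixels)))
})

setMethod("show", "CountResult", function(object) {
  cat(sprintf(
    "CountResult: %d object(s) (%d singleton, %d cluster) -> %d nuclei [%s complexity]\n",
    object@nObjects, object@nSingletons, object@nClusters,
    object@estimatedNuclei, object@complexity))
})

setMethod("show", "SyntheticScene", function(object) {
  npos <- sum(object@nuclei$class != "NEG")
  cat(sprintf(
    "SyntheticScene %d x %d px: %d positive, %d negative nuclei, background %s (seed %d)\n",
    dim(object@image)[1], dim(object@image)[2], npos,
    sum(object@nuclei$class == "NEG"), object@backgroundLevel, object@seed))
})

setMethod("show", "AgreementSummary", function(object) {
  cat(sprintf(
    "AgreementSummary (n = %d): mean diff %.3f, SD %.3f, LoA [%.3f, %.3f]\n",
    object@n, object@meanDiff, object@sdDiff, object@loaLow, object@loaHigh))
})

setMethod("show", "DifferenceCurve", function(object) {
  cat(sprintf("DifferenceCurve over %d pair(s); P(|diff| >= d) at %d threshold(s)\n",
              length(object@absDiffs), nrow(object@curve)))
})
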