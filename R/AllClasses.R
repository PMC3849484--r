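#' Inclusive per-channel RGB color range
#'
#' A stain class is defined by an axis-aligned box in RGB space: a pixel
#' belongs to the class when each of its three channels lies inside the
#' corresponding inclusive bound. This is the segmentation primitive of the
#' whole procedure; no color-space conversion or stain deconvolution is
#' performed.
#'
#' @slot lo integer(3), lower bounds (R, G, B), each in [0, 255].
#' @slot hi integer(3), upper bounds (R, G, B), each in [0, 255].
#' @export
setClass("ColorRange", representation(lo = "integer", hi = "integer"))

setValidity("ColorRange", function(object) {
  if (length(object@lo) != 3L || length(object@hi) != 3L)
    return("lo and hi must each have length 3 (R, G, B)")
  if (anyNA(object@lo) || anyNA(object@hi))
    return("bounds must not be NA")
  if (any(object@lo < 0L) || any(object@hi > 255L))
    return("bounds must lie in [0, 255]")
  if (any(object@lo > object@hi))
    return("each channel must satisfy lo <= hi")
  TRUE
})

#' Construct a ColorRange
#'
#' @param r,g,b numeric(2): inclusive (lo, hi) bounds for the red, green and
#'   blue channel, in [0, 255].
#' @return A [ColorRange-class] object.
#' @examples
#' darkBrown <- colorRange(r = c(40, 120), g = c(20, 90), b = c(0, 70))
#' @export
colorRange <- function(r, g, b) {
  new("ColorRange",
      lo = as.integer(c(r[1], g[1], b[1])),
      hi = as.integer(c(r[2], g[2], b[2])))
}

#' Morphological gate on object area and roundness
#'
#' Objects are retained when their pixel area (px^2) and roundness
#' (perimeter^2 / (4 * pi * area), 1 for a perfect circle) both fall inside
#' the inclusive bounds.
#'
#' @slot areaMin,areaMax numeric(1), area bounds in px^2.
#' @slot roundnessMin,roundnessMax numeric(1), roundness bounds (>= 1).
#' @export
setClass("MorphFilter", representation(
  areaMin = "numeric", areaMax = "numeric",
  roundnessMin = "numeric", roundnessMax = "numeric"))

setValidity("MorphFilter", function(object) {
  if (object@areaMin > object@areaMax) return("areaMin must be <= areaMax")
  if (object@areaMin < 0) return("areaMin must be >= 0")
  if (object@roundnessMin < 1) return("roundnessMin must be >= 1")
  if (object@roundnessMin > object@roundnessMax)
    return("roundnessMin must be <= roundnessMax")
  TRUE
})

#' Construct a MorphFilter
#'
#' @param area numeric(2), inclusive (min, max) object area in px^2.
#' @param roundness numeric(2), inclusive (min, max) roundness; the minimum
#'   must be >= 1 (a perfect circle).
#' @return A [MorphFilter-class] object.
#' @export
morphFilter <- function(area = c(1, Inf), roundness = c(1, Inf)) {
  new("MorphFilter",
      areaMin = as.numeric(area[1]), areaMax = as.numeric(area[2]),
      roundnessMin = as.numeric(roundness[1]),
      roundnessMax = as.numeric(roundness[2]))
}

#' Run configuration for the multistep procedure
#'
#' Holds the seven color ranges, the per-step morphology filters, the
#' background ratio threshold, the sentinel color used to displace masked
#' pixels out of every positive range, and the counting parameters. Use
#' [defaultConfig()] or [loadConfig()] to obtain a validated instance.
#'
#' @slot ranges named list of [ColorRange-class]: `darkest`, `mid`, `light`
#'   (the three positive brown passes), `negative` (hematoxylin blue),
#'   `widePositive` (the old wide-range macro), `bg1`, `bg2` (the two
#'   background assessment ranges).
#' @slot filters named list of [MorphFilter-class]: `map1`, `map2`, `map3`,
#'   `final`, `wide`.
#' @slot ratioThreshold numeric(1), area2/area1 cut between LOW and HIGH
#'   background (ties go to HIGH).
#' @slot sentinelColor integer(3), RGB triplet outside every positive range.
#' @slot meanNucleusArea numeric(1), px^2; `NA` means estimate per image
#'   ("auto").
#' @slot clusterFactor numeric(1), objects larger than
#'   `clusterFactor * meanNucleusArea` are treated as clusters.
#' @slot complexityCutoff integer(1), estimated-nuclei cut between LOW and
#'   HIGH image complexity (<= cutoff is LOW).
#' @slot fillHoles logical(1), fill holes inside objects before morphometry.
#' @slot excludeBorder logical(1), drop objects touching the image border.
#' @export
setClass("RunConfig", representation(
  ranges = "list", filters = "list",
  ratioThreshold = "numeric", sentinelColor = "integer",
  meanNucleusArea = "numeric", clusterFactor = "numeric",
  complexityCutoff = "integer", fillHoles = "logical",
  excludeBorder = "logical"))

.POSITIVE_RANGES <- c("darkest", "mid", "light", "widePositive")
.RANGE_NAMES <- c(.POSITIVE_RANGES[1:3], "negative", "widePositive", "bg1", "bg2")
.FILTER_NAMES <- c("map1", "map2", "map3", "final", "wide")

setValidity("RunConfig", function(object) {
  if (!all(.RANGE_NAMES %in% names(object@ranges)))
    return(paste("ranges must contain:", paste(.RANGE_NAMES, collapse = ", ")))
  for (nm in .RANGE_NAMES) {
    v <- validObject(object@ranges[[nm]], test = TRUE)
    if (!isTRUE(v)) return(paste0("range '", nm, "': ", v))
  }
  if (!all(.FILTER_NAMES %in% names(object@filters)))
    return(paste("filters must contain:", paste(.FILTER_NAMES, collapse = ", ")))
  for (nm in .FILTER_NAMES) {
    v <- validObject(object@filters[[nm]], test = TRUE)
    if (!isTRUE(v)) return(paste0("filter '", nm, "': ", v))
  }
  if (!(object@ratioThreshold > 0))
    return("ratioThreshold must be > 0")
  if (length(object@sentinelColor) != 3L ||
      any(object@sentinelColor < 0L) || any(object@sentinelColor > 255L))
    return("sentinelColor must be an RGB triplet in [0, 255]")
  for (nm in .POSITIVE_RANGES) {
    rg <- object@ranges[[nm]]
    if (all(object@sentinelColor >= rg@lo & object@sentinelColor <= rg@hi))
      return(paste0("sentinelColor lies inside positive range '", nm, "'"))
  }
  if (!is.na(object@meanNucleusArea) && object@meanNucleusArea <= 0)
    return("meanNucleusArea must be > 0 (or NA for auto)")
  if (object@clusterFactor <= 0) return("clusterFactor must be > 0")
  if (object@complexityCutoff < 1L) return("complexityCutoff must be >= 1")
  TRUE
})

#' Labeled object map with per-object morphometry
#'
#' The result of one segmentation pass: a binary mask, the list of pixel
#' sets of its 8-connected components, and a feature table (area, perimeter,
#' roundness, centroid, mean color) with labels 1..n assigned in row-major
#' scan order of each object's first pixel.
#'
#' @slot mask logical matrix (height x width).
#' @slot pixels list of integer vectors; column-major linear indices of each
#'   object's pixels.
#' @slot features data.frame with columns `label`, `area`, `perimeter`,
#'   `roundness`, `centroidRow`, `centroidCol`, `meanR`, `meanG`, `meanB`.
#' @slot stepTag character(1), one of MAP1, MAP2, MAP3, FINAL, WIDE, MAP4.
#' @export
setClass("ObjectMap", representation(
  mask = "matrix", pixels = "list", features = "data.frame",
  stepTag = "character"))

.STEP_TAGS <- c("MAP1", "MAP2", "MAP3", "FINAL", "WIDE", "MAP4")

setValidity("ObjectMap", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  if (!object@stepTag %in% .STEP_TAGS)
    return(paste("stepTag must be one of:", paste(.STEP_TAGS, collapse = ", ")))
  n <- length(object@pixels)
  if (nrow(object@features) != n)
    return("features must have one row per object")
  if (n > 0 && !identical(object@features$label, seq_len(n)))
    return("labels must be contiguous from 1")
  px <- as.integer(unlist(object@pixels, use.names = FALSE))
  if (length(px) != sum(object@mask) ||
      !identical(sort(px), which(object@mask)))
    return("union of object pixel sets must equal the mask's true set")
  if (n > 0 && any(object@features$area < 1)) return("object areas must be >= 1")
  TRUE
})

#' Background assessment of one image
#'
#' After the three positive selection passes, the brown stain left
#' unselected is measured with two color ranges: `area1` (primary brown
#' support outside the selected objects) and `area2` (the paler diffuse
#' background indicator, disjoint from the primary support). `area2 == 0`
#' means no background (class NONE); otherwise the ratio `area2 / area1`
#' below the configured threshold is LOW, at or above it HIGH. By
#' convention `area1 == 0` with `area2 > 0` is HIGH (ratio `Inf`).
#'
#' @slot area1,area2 numeric(1), px^2.
#' @slot ratio numeric(1); 0 when `area2 == 0`.
#' @slot backgroundClass character(1), one of NONE, LOW, HIGH.
#' @export
setClass("BackgroundAssessment", representation(
  area1 = "numeric", area2 = "numeric", ratio = "numeric",
  backgroundClass = "character"))

setValidity("BackgroundAssessment", function(object) {
  if (object@area1 < 0 || object@area2 < 0) return("areas must be >= 0")
  if (!object@backgroundClass %in% c("NONE", "LOW", "HIGH"))
    return("backgroundClass must be NONE, LOW or HIGH")
  if ((object@area2 == 0) != (object@backgroundClass == "NONE"))
    return("backgroundClass is NONE iff area2 == 0")
  TRUE
})

#' Result of running one macro on one image
#'
#' @slot macroUsed character(1), one of NONE_BG, RESTRICTIVE, FULL.
#' @slot selected [ObjectMap-class], the selected positive objects (the
#'   union of the step maps actually run; tag MAP4 for multistep macros).
#' @slot assessment [BackgroundAssessment-class].
#' @slot stepMaps named list of [ObjectMap-class], the constitutive step
#'   maps (`wide` for NONE_BG; `map1`..`map3` for RESTRICTIVE; plus `final`
#'   for FULL).
#' @export
setClass("MacroResult", representation(
  macroUsed = "character", selected = "ObjectMap",
  assessment = "BackgroundAssessment", stepMaps = "list"))

setValidity("MacroResult", function(object) {
  if (!object@macroUsed %in% c("NONE_BG", "RESTRICTIVE", "FULL"))
    return("macroUsed must be NONE_BG, RESTRICTIVE or FULL")
  if (length(object@stepMaps) > 0) {
    u <- Reduce(`|`, lapply(object@stepMaps, function(m) m@mask))
    if (!identical(u, object@selected@mask))
      return("selected mask must equal the union of the step maps run")
  }
  TRUE
})

#' Nucleus count estimated from selected object areas
#'
#' @slot nObjects,nSingletons,nClusters integer(1).
#' @slot estimatedNuclei integer(1).
#' @slot meanNucleusAreaUsed numeric(1), px^2.
#' @slot complexity character(1), LOW (estimated nuclei <= cutoff) or HIGH.
#' @export
setClass("CountResult", representation(
  nObjects = "integer", nSingletons = "integer", nClusters = "integer",
  estimatedNuclei = "integer", meanNucleusAreaUsed = "numeric",
  complexity = "character"))

setValidity("CountResult", function(object) {
  if (object@nSingletons + object@nClusters != object@nObjects)
    return("singletons + clusters must equal nObjects")
  if (object@estimatedNuclei < object@nObjects)
    return("estimatedNuclei must be >= nObjects")
  if (!object@complexity %in% c("LOW", "HIGH"))
    return("complexity must be LOW or HIGH")
  TRUE
})

#' Synthetic IHC scene with ground truth
#'
#' @slot image integer array (height x width x 3), channels in [0, 255].
#' @slot nuclei data.frame, one row per nucleus: `centerRow`, `centerCol`,
#'   `a`, `b` (ellipse semi-axes, px), `theta` (orientation, rad), `class`
#'   (POS_DARK, POS_MID, POS_LIGHT or NEG).
#' @slot backgroundLevel character(1), none/low/high.
#' @slot backgroundPixels logical matrix, the visible spurious-stain pixels.
#' @slot seed integer(1).
#' @export
setClass("SyntheticScene", representation(
  image = "array", nuclei = "data.frame", backgroundLevel = "character",
  backgroundPixels = "matrix", seed = "integer"))

setValidity("SyntheticScene", function(object) {
  if (!object@backgroundLevel %in% c("none", "low", "high"))
    return("backgroundLevel must be none, low or high")
  if (object@backgroundLevel == "none" && any(object@backgroundPixels))
    return("background_level none implies no background pixels")
  TRUE
})

#' Bland-Altman agreement summary
#'
#' Differences are `countA - countB`; limits of agreement are
#' `meanDiff +/- multiplier * sdDiff` (sample SD, n-1 denominator).
#'
#' @slot n integer(1), number of image pairs.
#' @slot meanDiff,sdDiff,loaLow,loaHigh numeric(1), in nuclei.
#' @slot multiplier numeric(1), the limits-of-agreement multiplier.
#' @slot points data.frame with columns `imageId`, `pairMean`, `diff`.
#' @export
setClass("AgreementSummary", representation(
  n = "integer", meanDiff = "numeric", sdDiff = "numeric",
  loaLow = "numeric", loaHigh = "numeric", multiplier = "numeric",
  points = "data.frame"))

setValidity("AgreementSummary", function(object) {
  if (object@loaLow > object@meanDiff || object@meanDiff > object@loaHigh)
    return("limits of agreement must bracket the mean difference")
  TRUE
})

#' Empirical survival curve of absolute paired count differences
#'
#' Step function P(|diff| >= d) evaluated at d = 0 and every distinct
#' observed absolute difference.
#'
#' @slot curve data.frame with columns `d` (ascending) and `prob`.
#' @slot absDiffs numeric, the observed absolute differences (for exact
#'   evaluation at arbitrary thresholds).
#' @export
setClass("DifferenceCurve", representation(
  curve = "data.frame", absDiffs = "numeric"))

setValidity("DifferenceCurve", function(object) {
  p <- object@curve$prob
  d <- object@curve$d
  if (length(d) == 0 || d[1] != 0) return("curve must start at d = 0")
  if (p[1] != 1) return("P at d = 0 must be 1")
  if (is.unsorted(d, strictly = TRUE)) return("thresholds must be ascending")
  if (any(diff(p) > 0)) return("probabilities must be non-increasing")
  if (any(p < 0 | p > 1)) return("probabilities must lie in [0, 1]")
  TRUE
})
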