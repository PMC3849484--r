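# round half away from zero, so 2.5 -> 3 and 3.4 -> 3 on every platform
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Estimate the mean single-nucleus area
#'
#' A fixed `meanNucleusArea` in the configuration is passed through. In
#' "auto" mode (the default, `NA` in the config) the estimate is the median
#' area of the round objects (roundness <= 1.3), which excludes elongated
#' clusters; if no round object exists the documented fallback of 450 px^2
#' (a typical nucleus of ~12 px radius) is used.
#'
#' @param objects an [ObjectMap-class].
#' @param cfg a [RunConfig-class].
#' @return numeric(1), px^2.
#' @export
estimateMeanNucleusArea <- function(objects, cfg = defaultConfig()) {
  stopifnot(is(objects, "ObjectMap"), is(cfg, "RunConfig"))
  if (!is.na(cfg@meanNucleusArea)) return(cfg@meanNucleusArea)
  f <- objects@features
  roundAreas <- f$area[f$roundness <= 1.3]
  if (length(roundAreas) == 0) return(.MEAN_AREA_FALLBACK)
  median(roundAreas)
}

#' Estimate the number of positive nuclei from object areas
#'
#' The macros select individual nuclei and clusters as single objects; the
#' count is recovered from their areas. An object is a cluster when its
#' area exceeds `clusterFactor * meanArea` (default factor 1.5); a
#' singleton contributes 1 nucleus and a cluster contributes
#' `round(area / meanArea)` (half away from zero) with a minimum of 2.
#'
#' @param objects an [ObjectMap-class] (e.g. `selectedObjects(result)`).
#' @param meanArea mean single-nucleus area in px^2; defaults to
#'   [estimateMeanNucleusArea()].
#' @param cfg a [RunConfig-class].
#' @return a [CountResult-class].
#' @examples
#' scn <- generateScene(nPositive = 15, seed = 3)
#' res <- analyzeImage(scn)
#' countNuclei(selectedObjects(res))
#' @export
countNuclei <- function(objects, meanArea = estimateMeanNucleusArea(objects, cfg),
                        cfg = defaultConfig()) {
  stopifnot(is(objects, "ObjectMap"), is(cfg, "RunConfig"))
  if (!is.numeric(meanArea) || is.na(meanArea) || meanArea <= 0)
    stop("meanArea must be a positive number", call. = FALSE)
  areas <- objects@features$area
  isCluster <- areas > cfg@clusterFactor * meanArea
  contrib <- ifelse(isCluster,
                    pmax(2, .roundHalfAway(areas / meanArea)), 1)
  est <- as.integer(sum(contrib))
  new("CountResult",
      nObjects = length(areas),
      nSingletons = as.integer(sum(!isCluster)),
      nClusters = as.integer(sum(isCluster)),
      estimatedNuclei = est,
      meanNucleusAreaUsed = meanArea,
      complexity = classifyComplexity(est, cfg@complexityCutoff))
}

#' Classify image complexity by positive-nuclei load
#'
#' LOW when the estimated count is at most the cutoff (default 100 nuclei
#' per image), HIGH above it.
#'
#' @param estimatedNuclei non-negative count(s).
#' @param cutoff positive count, default 100.
#' @return character vector of "LOW"/"HIGH".
#' @examples
#' classifyComplexity(c(100, 101))  # "LOW" "HIGH"
#' @export
classifyComplexity <- function(estimatedNuclei, cutoff = 100) {
  stopifnot(all(estimatedNuclei >= 0), cutoff >= 1)
  ifelse(estimatedNuclei <= cutoff, "LOW", "HIGH")
}
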