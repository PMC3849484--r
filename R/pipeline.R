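#' @title The multistep positive-selection procedure
#' @description Internal helpers building the three positive object maps.
#' Step 1 displaces negative (hematoxylin blue) and light positive pixels to
#' the sentinel color, then segments the darkest brown range (objects
#' map 1). Steps 2 and 3 displace only negatives plus the pixels already
#' selected, then segment the mid and light brown ranges. Each map is gated
#' by its own morphology filter, and the three maps are pixel-disjoint by
#' construction.
#' @name pipeline-internals
#' @keywords internal
NULL

#' Build objects map 1 (darkest positive nuclei)
#'
#' Masks negative and light-positive pixels with the sentinel color,
#' segments the darkest brown range, labels and applies the MAP1 morphology
#' filter.
#'
#' @param image integer array `height x width x 3`.
#' @param cfg a [RunConfig-class].
#' @return an [ObjectMap-class] tagged MAP1.
#' @export
buildMap1 <- function(image, cfg) {
  stopifnot(is(cfg, "RunConfig"))
  negMask <- segmentByColor(image, cfg@ranges$negative)
  lightMask <- segmentByColor(image, cfg@ranges$light)
  src <- applySentinelMask(image, negMask | lightMask, cfg@sentinelColor)
  m <- segmentByColor(src, cfg@ranges$darkest)
  filterObjects(
    labelObjects(m, image, "MAP1", cfg@fillHoles, cfg@excludeBorder),
    cfg@filters$map1)
}

#' Build objects maps 2 and 3 (mid and light positive nuclei)
#'
#' Each step masks negative pixels plus everything selected in earlier
#' steps, segments its own brown range (mid for map 2, light for map 3) and
#' gates on its morphology filter. The returned maps are pixel-disjoint
#' with each other and with the prior maps.
#'
#' @param image integer array `height x width x 3`.
#' @param prior a single [ObjectMap-class] or list of maps from earlier
#'   steps (normally map 1).
#' @param cfg a [RunConfig-class].
#' @return list with elements `map2` and `map3`.
#' @export
buildMaps23 <- function(image, prior, cfg) {
  stopifnot(is(cfg, "RunConfig"))
  if (is(prior, "ObjectMap")) prior <- list(prior)
  priorMask <- maskUnion(lapply(prior, objectMask))
  negMask <- segmentByColor(image, cfg@ranges$negative)
  src2 <- applySentinelMask(image, negMask | priorMask, cfg@sentinelColor)
  map2 <- filterObjects(
    labelObjects(segmentByColor(src2, cfg@ranges$mid), image, "MAP2",
                 cfg@fillHoles, cfg@excludeBorder),
    cfg@filters$map2)
  src3 <- applySentinelMask(image, negMask | priorMask | map2@mask,
                            cfg@sentinelColor)
  map3 <- filterObjects(
    labelObjects(segmentByColor(src3, cfg@ranges$light), image, "MAP3",
                 cfg@fillHoles, cfg@excludeBorder),
    cfg@filters$map3)
  list(map2 = map2, map3 = map3)
}

#' Assess the spurious background of an image
#'
#' The brown color not selected as positive objects is segmented with two
#' ranges: `area1` is the primary brown support (`bg1`) outside the
#' selected mask; `area2` is the paler indicator support (`bg2`) outside
#' both the selected mask and the `bg1` support, so the two measurements
#' are disjoint. `area2 == 0` classifies the image as NONE (no background);
#' otherwise `ratio = area2 / area1` below the configured threshold is LOW
#' and at or above it HIGH (`area1 == 0` with `area2 > 0` is HIGH, ratio
#' `Inf`).
#'
#' @param image integer array `height x width x 3`.
#' @param selected logical matrix, the union of positive maps 1-3.
#' @param cfg a [RunConfig-class].
#' @return a [BackgroundAssessment-class].
#' @export
assessBackground <- function(image, selected, cfg) {
  stopifnot(is(cfg, "RunConfig"))
  if (!is.logical(selected) || !identical(dim(selected), dim(image)[1:2]))
    stop("selected mask dimensions must match the image", call. = FALSE)
  bg1 <- segmentByColor(image, cfg@ranges$bg1)
  bg2 <- segmentByColor(image, cfg@ranges$bg2)
  area1 <- sum(bg1 & !selected)
  area2 <- sum(bg2 & !selected & !bg1)
  if (area2 == 0) {
    cls <- "NONE"; ratio <- 0
  } else if (area1 == 0) {
    cls <- "HIGH"; ratio <- Inf
  } else {
    ratio <- area2 / area1
    cls <- if (ratio < cfg@ratioThreshold) "LOW" else "HIGH"
  }
  new("BackgroundAssessment", area1 = as.numeric(area1),
      area2 = as.numeric(area2), ratio = ratio, backgroundClass = cls)
}

.buildMaps123 <- function(image, cfg) {
  map1 <- buildMap1(image, cfg)
  m23 <- buildMaps23(image, map1, cfg)
  list(map1 = map1, map2 = m23$map2, map3 = m23$map3)
}

.assessFromMaps <- function(image, maps, cfg) {
  assessBackground(image, maskUnion(lapply(maps, objectMask)), cfg)
}

#' Run the no-background (wide-range) macro
#'
#' The single-pass macro for clean images: negatives are displaced to the
#' sentinel color, the wide positive range (darkest to lightest brown) is
#' segmented in one pass and gated by the wide morphology filter.
#'
#' @param image integer array `height x width x 3`.
#' @param cfg a [RunConfig-class].
#' @param assessment optional [BackgroundAssessment-class] to attach; when
#'   `NULL` it is computed from maps 1-3 exactly as [analyzeImage()] does.
#'   Supplying it lets the macro be forced on any image (e.g. for method
#'   comparison) without repeating the assessment.
#' @return a [MacroResult-class] with `macroUsed == "NONE_BG"`.
#' @export
runNoneBgMacro <- function(image, cfg, assessment = NULL) {
  stopifnot(is(cfg, "RunConfig"))
  if (is.null(assessment))
    assessment <- .assessFromMaps(image, .buildMaps123(image, cfg), cfg)
  negMask <- segmentByColor(image, cfg@ranges$negative)
  src <- applySentinelMask(image, negMask, cfg@sentinelColor)
  wide <- filterObjects(
    labelObjects(segmentByColor(src, cfg@ranges$widePositive), image, "WIDE",
                 cfg@fillHoles, cfg@excludeBorder),
    cfg@filters$wide)
  new("MacroResult", macroUsed = "NONE_BG", selected = wide,
      assessment = assessment, stepMaps = list(wide = wide))
}

#' Run the restrictive macro (low background)
#'
#' Selection is the union of the three positive maps; no final pass.
#'
#' @inheritParams runNoneBgMacro
#' @param maps optional precomputed list `map1`/`map2`/`map3`.
#' @return a [MacroResult-class] with `macroUsed == "RESTRICTIVE"`.
#' @export
runRestrictiveMacro <- function(image, cfg, assessment = NULL, maps = NULL) {
  stopifnot(is(cfg, "RunConfig"))
  if (is.null(maps)) maps <- .buildMaps123(image, cfg)
  if (is.null(assessment)) assessment <- .assessFromMaps(image, maps, cfg)
  new("MacroResult", macroUsed = "RESTRICTIVE",
      selected = .combineMaps(maps), assessment = assessment,
      stepMaps = maps)
}

#' Run the full macro (high background)
#'
#' Maps 1-3 are supplemented with a final pass that segments the light
#' positive range after displacing negatives, all prior selections and the
#' diffuse-background indicator support (`bg2` outside `bg1`), gated by the
#' strict FINAL morphology filter (tight roundness band) so that only the
#' clearest compact objects are added.
#'
#' @inheritParams runRestrictiveMacro
#' @return a [MacroResult-class] with `macroUsed == "FULL"`.
#' @export
runFullMacro <- function(image, cfg, assessment = NULL, maps = NULL) {
  stopifnot(is(cfg, "RunConfig"))
  if (is.null(maps)) maps <- .buildMaps123(image, cfg)
  if (is.null(assessment)) assessment <- .assessFromMaps(image, maps, cfg)
  selected123 <- maskUnion(lapply(maps, objectMask))
  negMask <- segmentByColor(image, cfg@ranges$negative)
  bg2support <- segmentByColor(image, cfg@ranges$bg2) &
                !segmentByColor(image, cfg@ranges$bg1)
  src <- applySentinelMask(image, negMask | selected123 | bg2support,
                           cfg@sentinelColor)
  finalMap <- filterObjects(
    labelObjects(segmentByColor(src, cfg@ranges$light), image, "FINAL",
                 cfg@fillHoles, cfg@excludeBorder),
    cfg@filters$final)
  allMaps <- c(maps, list(final = finalMap))
  new("MacroResult", macroUsed = "FULL", selected = .combineMaps(allMaps),
      assessment = assessment, stepMaps = allMaps)
}

#' Analyze one image with the automated multistep procedure
#'
#' Builds positive object maps 1-3, assesses the unselected brown stain
#' with the two background ranges, and routes the image to exactly one
#' macro: NONE (`area2 == 0`) re-segments with the wide-range macro,
#' LOW (`ratio` below the threshold) keeps the union of maps 1-3, HIGH runs
#' the full macro with the strict final pass. Deterministic: a pure
#' function of the image and configuration.
#'
#' @param image integer array `height x width x 3`, or a
#'   [SyntheticScene-class] (its image is used).
#' @param cfg a [RunConfig-class]; defaults to [defaultConfig()].
#' @return a [MacroResult-class].
#' @examples
#' scn <- generateScene(nPositive = 12, nNegative = 6, seed = 7)
#' res <- analyzeImage(scn)
#' macroUsed(res)
#' nObjects(res)
#' @export
analyzeImage <- function(image, cfg = defaultConfig()) {
  if (is(image, "SyntheticScene")) image <- image@image
  .checkImage(image)
  stopifnot(is(cfg, "RunConfig"))
  maps <- .buildMaps123(image, cfg)
  assessment <- .assessFromMaps(image, maps, cfg)
  switch(assessment@backgroundClass,
    NONE = runNoneBgMacro(image, cfg, assessment),
    LOW = runRestrictiveMacro(image, cfg, assessment, maps),
    HIGH = runFullMacro(image, cfg, assessment, maps))
}
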