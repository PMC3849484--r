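#' Default run configuration
#'
#' The shipped defaults are calibrated to the synthetic scene generator's
#' stain palette (see [generateScene()]); a real-slide deployment is
#' expected to recalibrate the color ranges to its own staining. The three
#' positive brown ranges are disjoint by construction (dark, mid, light),
#' `widePositive` is their bounding hull (the wide range of the old
#' single-pass macro), `bg1` equals the wide positive hull and `bg2` extends
#' the light range towards the paler hues typical of diffuse spurious
#' background.
#'
#' @return A validated [RunConfig-class] object.
#' @examples
#' cfg <- defaultConfig()
#' cfg
#' @export
defaultConfig <- function() {
  ranges <- list(
    darkest      = colorRange(r = c(40, 120),  g = c(20, 90),   b = c(0, 70)),
    mid          = colorRange(r = c(121, 170), g = c(80, 130),  b = c(40, 100)),
    light        = colorRange(r = c(171, 215), g = c(120, 170), b = c(70, 135)),
    negative     = colorRange(r = c(60, 160),  g = c(70, 170),  b = c(130, 230)),
    widePositive = colorRange(r = c(40, 215),  g = c(20, 170),  b = c(0, 135)),
    bg1          = colorRange(r = c(40, 215),  g = c(20, 170),  b = c(0, 135)),
    bg2          = colorRange(r = c(171, 230), g = c(120, 185), b = c(70, 150)))
  filters <- list(
    map1  = morphFilter(area = c(80, 5000), roundness = c(1, 3)),
    map2  = morphFilter(area = c(80, 5000), roundness = c(1, 3)),
    map3  = morphFilter(area = c(80, 5000), roundness = c(1, 3)),
    final = morphFilter(area = c(80, 1200), roundness = c(1, 1.6)),
    wide  = morphFilter(area = c(80, 5000), roundness = c(1, 3)))
  new("RunConfig",
      ranges = ranges, filters = filters,
      ratioThreshold = 0.2, sentinelColor = c(0L, 255L, 0L),
      meanNucleusArea = NA_real_, clusterFactor = 1.5,
      complexityCutoff = 100L, fillHoles = FALSE, excludeBorder = FALSE)
}

# px^2 used by estimateMeanNucleusArea when "auto" finds no round object
.MEAN_AREA_FALLBACK <- 450

.rangeToList <- function(rg) {
  list(r = c(rg@lo[1], rg@hi[1]), g = c(rg@lo[2], rg@hi[2]),
       b = c(rg@lo[3], rg@hi[3]))
}

.rangeFromList <- function(x, name) {
  for (ch in c("r", "g", "b"))
    if (is.null(x[[ch]]) || length(x[[ch]]) != 2L)
      stop("config range '", name, "' must give 2-element r, g and b bounds",
           call. = FALSE)
  rg <- try(colorRange(r = x$r, g = x$g, b = x$b), silent = TRUE)
  if (inherits(rg, "try-error"))
    stop("config range '", name, "' is invalid: ",
         attr(rg, "condition")$message, call. = FALSE)
  rg
}

.filterFromList <- function(x, name) {
  area <- if (is.null(x$area)) c(1, Inf) else as.numeric(x$area)
  rnd <- if (is.null(x$roundness)) c(1, Inf) else as.numeric(x$roundness)
  f <- try(morphFilter(area = area, roundness = rnd), silent = TRUE)
  if (inherits(f, "try-error"))
    stop("config filter '", name, "' is invalid: ",
         attr(f, "condition")$message, call. = FALSE)
  f
}

#' Load a run configuration from a YAML file
#'
#' Keys missing from the file keep their [defaultConfig()] values; the
#' merged configuration is validated as a whole (channel bounds ordered,
#' sentinel color outside every positive range, positive ratio threshold).
#' An empty file yields the defaults. `mean_nucleus_area` may be a number
#' (px^2) or the string `"auto"`.
#'
#' @param path path to a YAML key-value file.
#' @return A validated [RunConfig-class] object.
#' @seealso [dumpConfig()] for the inverse; load-dump-load is idempotent.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  cfg <- defaultConfig()
  for (nm in names(raw$ranges)) {
    if (!nm %in% .RANGE_NAMES)
      stop("unknown color range in config: '", nm, "'", call. = FALSE)
    cfg@ranges[[nm]] <- .rangeFromList(raw$ranges[[nm]], nm)
  }
  for (nm in names(raw$filters)) {
    if (!nm %in% .FILTER_NAMES)
      stop("unknown filter in config: '", nm, "'", call. = FALSE)
    cfg@filters[[nm]] <- .filterFromList(raw$filters[[nm]], nm)
  }
  if (!is.null(raw$ratio_threshold))
    cfg@ratioThreshold <- as.numeric(raw$ratio_threshold)
  if (!is.null(raw$sentinel_color))
    cfg@sentinelColor <- as.integer(raw$sentinel_color)
  if (!is.null(raw$mean_nucleus_area))
    cfg@meanNucleusArea <- if (identical(raw$mean_nucleus_area, "auto"))
      NA_real_ else as.numeric(raw$mean_nucleus_area)
  if (!is.null(raw$cluster_factor))
    cfg@clusterFactor <- as.numeric(raw$cluster_factor)
  if (!is.null(raw$complexity_cutoff))
    cfg@complexityCutoff <- as.integer(raw$complexity_cutoff)
  if (!is.null(raw$fill_holes)) cfg@fillHoles <- isTRUE(raw$fill_holes)
  if (!is.null(raw$exclude_border))
    cfg@excludeBorder <- isTRUE(raw$exclude_border)
  v <- validObject(cfg, test = TRUE)
  if (!isTRUE(v)) stop("invalid configuration: ", v, call. = FALSE)
  cfg
}

#' Write a run configuration to a YAML file
#'
#' @param cfg a [RunConfig-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
dumpConfig <- function(cfg, path) {
  stopifnot(is(cfg, "RunConfig"))
  out <- list(
    ranges = lapply(cfg@ranges, .rangeToList),
    filters = lapply(cfg@filters, function(f)
      list(area = c(f@areaMin, f@areaMax),
           roundness = c(f@roundnessMin, f@roundnessMax))),
    ratio_threshold = cfg@ratioThreshold,
    sentinel_color = cfg@sentinelColor,
    mean_nucleus_area = if (is.na(cfg@meanNucleusArea)) "auto"
                        else cfg@meanNucleusArea,
    cluster_factor = cfg@clusterFactor,
    complexity_cutoff = cfg@complexityCutoff,
    fill_holes = cfg@fillHoles,
    exclude_border = cfg@excludeBorder)
  yaml::write_yaml(out, path)
  invisible(path)
}
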