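#' Label connected components and compute per-object morphometry
#'
#' Components are 8-connected; labels 1..n follow row-major scan order
#' (origin top-left) of each object's first pixel. Per object the area
#' (px^2), outer-boundary perimeter, roundness, centroid and mean color are
#' computed. The perimeter is the contour-step length of a clockwise
#' boundary trace (isothetic steps count 1, diagonal steps `sqrt(2)`);
#' roundness is `perimeter^2 / (4 * pi * area)`, clamped below at 1, with a
#' single pixel defined as 1.
#'
#' @param mask logical matrix.
#' @param image integer array matching `mask` (for per-object mean color).
#' @param stepTag one of MAP1, MAP2, MAP3, FINAL, WIDE, MAP4.
#' @param fillHoles fill enclosed background before labeling.
#' @param excludeBorder drop objects touching the image border.
#' @return an [ObjectMap-class].
#' @export
labelObjects <- function(mask, image, stepTag = "WIDE", fillHoles = FALSE,
                         excludeBorder = FALSE) {
  .checkImage(image)
  if (!is.logical(mask) || !identical(dim(mask), dim(image)[1:2]))
    stop("mask dimensions must match the image", call. = FALSE)
  if (fillHoles) mask <- .fillHoles(mask)
  labels <- .label8(mask)
  nlab <- max(labels)
  if (nlab > 0 && excludeBorder) {
    H <- nrow(mask); W <- ncol(mask)
    onBorder <- unique(c(labels[1, ], labels[H, ], labels[, 1], labels[, W]))
    onBorder <- onBorder[onBorder > 0]
    if (length(onBorder) > 0) {
      mask[labels %in% onBorder] <- FALSE
      labels <- .label8(mask)
      nlab <- max(labels)
    }
  }
  .objectMapFromLabels(mask, labels, nlab, image, stepTag)
}

.objectMapFromLabels <- function(mask, labels, nlab, image, stepTag) {
  if (nlab == 0) {
    return(new("ObjectMap", mask = mask, pixels = list(),
               features = .emptyFeatures(), stepTag = stepTag))
  }
  idx <- which(mask)
  lab <- labels[idx]
  pixels <- split(idx, lab)
  names(pixels) <- NULL
  area <- tabulate(lab, nlab)
  H <- nrow(mask)
  rows <- (idx - 1L) %% H + 1L
  cols <- (idx - 1L) %/% H + 1L
  perim <- .objectPerimeters(labels, nlab)
  roundness <- ifelse(area <= 1, 1, pmax(1, perim^2 / (4 * pi * area)))
  r <- image[, , 1][idx]; g <- image[, , 2][idx]; b <- image[, , 3][idx]
  features <- data.frame(
    label = seq_len(nlab),
    area = as.numeric(area),
    perimeter = perim,
    roundness = roundness,
    centroidRow = as.numeric(vapply(split(rows, lab), mean, numeric(1))),
    centroidCol = as.numeric(vapply(split(cols, lab), mean, numeric(1))),
    meanR = as.numeric(vapply(split(r, lab), mean, numeric(1))),
    meanG = as.numeric(vapply(split(g, lab), mean, numeric(1))),
    meanB = as.numeric(vapply(split(b, lab), mean, numeric(1))))
  new("ObjectMap", mask = mask, pixels = pixels, features = features,
      stepTag = stepTag)
}

.emptyFeatures <- function() {
  data.frame(label = integer(0), area = numeric(0), perimeter = numeric(0),
             roundness = numeric(0), centroidRow = numeric(0),
             centroidCol = numeric(0), meanR = numeric(0), meanG = numeric(0),
             meanB = numeric(0))
}

#' Roundness of a single object
#'
#' `perimeter^2 / (4 * pi * area)` with the perimeter estimated by the
#' clockwise boundary trace (steps 1 / `sqrt(2)`), clamped below at 1; a
#' single pixel has roundness 1 by convention.
#'
#' @param mask logical matrix containing exactly one connected (8-connected)
#'   non-empty pixel set.
#' @return numeric(1) >= 1.
#' @examples
#' m <- matrix(FALSE, 5, 60); m[3, 5:54] <- TRUE  # 1 x 50 line
#' computeRoundness(m)  # about 15.3
#' @export
computeRoundness <- function(mask) {
  if (!is.logical(mask) || sum(mask) == 0)
    stop("mask must contain a non-empty pixel set", call. = FALSE)
  labels <- .label8(mask)
  if (max(labels) != 1L)
    stop("mask must contain exactly one connected object", call. = FALSE)
  area <- sum(mask)
  if (area == 1L) return(1)
  p <- .objectPerimeters(labels, 1L)
  max(1, p^2 / (4 * pi * area))
}

#' Gate objects on area and roundness
#'
#' Retains exactly the objects whose area and roundness both lie inside the
#' filter's inclusive bounds; the mask is reduced to the retained pixels
#' and labels are recompacted (preserving order). Idempotent for a fixed
#' filter.
#'
#' @param map an [ObjectMap-class].
#' @param filter a [MorphFilter-class].
#' @return an [ObjectMap-class] with the retained objects.
#' @export
filterObjects <- function(map, filter) {
  stopifnot(is(map, "ObjectMap"), is(filter, "MorphFilter"))
  f <- map@features
  keep <- f$area >= filter@areaMin & f$area <= filter@areaMax &
          f$roundness >= filter@roundnessMin & f$roundness <= filter@roundnessMax
  if (all(keep)) return(map)
  pixels <- map@pixels[keep]
  mask <- map@mask
  mask[] <- FALSE
  mask[unlist(pixels, use.names = FALSE)] <- TRUE
  features <- f[keep, , drop = FALSE]
  features$label <- seq_len(nrow(features))
  rownames(features) <- NULL
  new("ObjectMap", mask = mask, pixels = pixels, features = features,
      stepTag = map@stepTag)
}

# Concatenate pixel-disjoint object maps (the paper's "objects map 4"):
# objects keep their per-step identity, labels recompacted in step order.
.combineMaps <- function(maps, stepTag = "MAP4") {
  mask <- maskUnion(lapply(maps, function(m) m@mask))
  pixels <- do.call(c, lapply(maps, function(m) m@pixels))
  if (length(pixels) != 0 &&
      length(unlist(pixels, use.names = FALSE)) != sum(mask))
    stop("step maps must be pixel-disjoint", call. = FALSE)
  features <- do.call(rbind, lapply(maps, function(m) m@features))
  if (is.null(features) || nrow(features) == 0) {
    features <- .emptyFeatures()
  } else {
    features$label <- seq_len(nrow(features))
    rownames(features) <- NULL
  }
  new("ObjectMap", mask = mask, pixels = if (is.null(pixels)) list() else pixels,
      features = features, stepTag = stepTag)
}
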