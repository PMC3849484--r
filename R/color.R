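#' Segment an image by an RGB color range
#'
#' The mask is true exactly where all three channels fall inside the
#' range's inclusive bounds.
#'
#' @param image integer array `height x width x 3`, channels in [0, 255].
#' @param range a [ColorRange-class].
#' @return logical matrix `height x width`.
#' @examples
#' img <- array(100L, c(4, 4, 3))
#' rg <- colorRange(r = c(90, 110), g = c(90, 110), b = c(90, 110))
#' sum(segmentByColor(img, rg))  # 16
#' @export
segmentByColor <- function(image, range) {
  .checkImage(image)
  stopifnot(is(range, "ColorRange"))
  image[, , 1] >= range@lo[1] & image[, , 1] <= range@hi[1] &
  image[, , 2] >= range@lo[2] & image[, , 2] <= range@hi[2] &
  image[, , 3] >= range@lo[3] & image[, , 3] <= range@hi[3]
}

#' Displace masked pixels to a sentinel color
#'
#' Returns a new image in which every masked pixel is replaced by the
#' sentinel RGB triplet and every other pixel is unchanged. The sentinel is
#' chosen (and validated at config load) to lie outside every positive
#' color range, so masked pixels can never be re-selected by a later
#' segmentation pass.
#'
#' @param image integer array `height x width x 3`.
#' @param mask logical matrix of the same height/width.
#' @param sentinel integer RGB triplet.
#' @return a new image array; the input is not modified.
#' @export
applySentinelMask <- function(image, mask, sentinel) {
  .checkImage(image)
  if (!is.logical(mask) || !identical(dim(mask), dim(image)[1:2]))
    stop("mask dimensions must match the image", call. = FALSE)
  sentinel <- as.integer(sentinel)
  stopifnot(length(sentinel) == 3L, all(sentinel >= 0L), all(sentinel <= 255L))
  out <- image
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[mask] <- sentinel[ch]
    out[, , ch] <- plane
  }
  out
}

#' Pixelwise union of binary masks
#'
#' @param masks non-empty list of logical matrices of identical dimensions.
#' @return logical matrix, the pixelwise OR.
#' @export
maskUnion <- function(masks) {
  if (!is.list(masks) || length(masks) == 0L)
    stop("masks must be a non-empty list", call. = FALSE)
  dims <- dim(masks[[1]])
  for (m in masks) {
    if (!is.logical(m) || !identical(dim(m), dims))
      stop("all masks must be logical matrices of identical dimensions",
           call. = FALSE)
  }
  Reduce(`|`, masks)
}
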