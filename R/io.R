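#' Read an 8-bit RGB image
#'
#' Reads a TIFF or PNG file into an integer array `height x width x 3` with
#' channels in [0, 255] (row-major, origin top-left). An alpha channel is
#' dropped; grayscale images are promoted to three identical channels.
#' Images with more than 8 bits per channel are rejected.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @return integer array `height x width x 3`.
#' @seealso [writeRGBImage()]; the round trip is bit-exact for 8-bit input.
#' @export
readRGBImage <- function(path) {
  if (!file.exists(path))
    stop("cannot read image, file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = , tiff = {
      x <- try(tiff::readTIFF(path, info = TRUE), silent = TRUE)
      if (inherits(x, "try-error"))
        stop("cannot decode TIFF image: ", path, call. = FALSE)
      bps <- attr(x, "bits.per.sample")
      if (!is.null(bps) && any(bps > 8L))
        stop("unsupported bit depth (> 8 bits/channel): ", path, call. = FALSE)
      x
    },
    png = {
      hdr <- readBin(path, "raw", n = 26L)
      if (length(hdr) >= 25L && as.integer(hdr[25L]) > 8L)
        stop("unsupported bit depth (> 8 bits/channel): ", path, call. = FALSE)
      x <- try(png::readPNG(path), silent = TRUE)
      if (inherits(x, "try-error"))
        stop("cannot decode PNG image: ", path, call. = FALSE)
      x
    },
    stop("unsupported image format '", ext, "' (TIFF or PNG expected): ",
         path, call. = FALSE))
  if (is.matrix(arr)) arr <- array(rep(arr, 3L), c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  img <- array(as.integer(round(arr * 255)), dim(arr))
  .checkImage(img)
  img
}

#' Write an 8-bit RGB image
#'
#' @param image integer array `height x width x 3`, channels in [0, 255].
#' @param path output path ending in `.tif`/`.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
writeRGBImage <- function(image, path) {
  .checkImage(image)
  ext <- tolower(tools::file_ext(path))
  ok <- switch(ext,
    tif = , tiff = tiff::writeTIFF(image / 255, path, bits.per.sample = 8L),
    png = { png::writePNG(image / 255, path); TRUE },
    stop("unsupported image format '", ext, "' (TIFF or PNG expected): ",
         path, call. = FALSE))
  if (!file.exists(path))
    stop("failed to write image: ", path, call. = FALSE)
  invisible(path)
}

.checkImage <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be a height x width x 3 array", call. = FALSE)
  if (dim(image)[1] < 1L || dim(image)[2] < 1L)
    stop("image has zero pixels", call. = FALSE)
  rng <- range(image)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop("image channels must lie in [0, 255]", call. = FALSE)
  invisible(TRUE)
}

.COUNT_COLS <- c("image_id", "macro_used", "n_objects", "total_object_area",
                 "estimated_nuclei")

.checkCountTable <- function(table) {
  if (!is.data.frame(table) || !all(.COUNT_COLS %in% names(table)))
    stop("count table must have columns: ",
         paste(.COUNT_COLS, collapse = ", "), call. = FALSE)
  if (nrow(table) > 0) {
    if (!all(table$macro_used %in% c("NONE_BG", "RESTRICTIVE", "FULL")))
      stop("macro_used must be NONE_BG, RESTRICTIVE or FULL", call. = FALSE)
    if (any(table$n_objects < 0))
      stop("n_objects must be >= 0", call. = FALSE)
    if (any(table$estimated_nuclei < table$n_objects))
      stop("estimated_nuclei must be >= n_objects", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a per-image count table as CSV
#'
#' Columns `image_id, macro_used, n_objects, total_object_area,
#' estimated_nuclei`, one row per image, UTF-8, '.' decimal separator.
#'
#' @param table data.frame as produced by [analyzeBatch()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(table, path) {
  .checkCountTable(table)
  con <- try(file(path, open = "w", encoding = "UTF-8"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop("cannot write count table: ", path, call. = FALSE)
  on.exit(close(con))
  write.csv(table[, .COUNT_COLS, drop = FALSE], con, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read a per-image count table from CSV
#'
#' @param path CSV path written by [writeCountTable()].
#' @return validated data.frame.
#' @export
readCountTable <- function(path) {
  if (!file.exists(path))
    stop("count table not found: ", path, call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  .checkCountTable(tab)
  tab$image_id <- as.character(tab$image_id)
  tab
}
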