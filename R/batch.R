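#' Analyze a batch of images into a count table
#'
#' Runs [analyzeImage()] and [countNuclei()] on each input and assembles
#' the per-image count table (`image_id, macro_used, n_objects,
#' total_object_area, estimated_nuclei`).
#'
#' @param images character vector of image paths, or a list of image
#'   arrays / [SyntheticScene-class] objects.
#' @param cfg a [RunConfig-class].
#' @param imageIds optional character ids; defaults to file names (for
#'   paths) or `image_1`, `image_2`, ...
#' @param verbose emit one log line per image (background class, areas,
#'   ratio, macro used).
#' @return data.frame, the count table.
#' @export
analyzeBatch <- function(images, cfg = defaultConfig(), imageIds = NULL,
                         verbose = FALSE) {
  fromPaths <- is.character(images)
  n <- length(images)
  if (is.null(imageIds)) {
    imageIds <- if (fromPaths)
      tools::file_path_sans_ext(basename(images))
    else paste0("image_", seq_len(n))
  }
  stopifnot(length(imageIds) == n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    img <- if (fromPaths) readRGBImage(images[[i]]) else images[[i]]
    res <- analyzeImage(img, cfg)
    sel <- res@selected
    cnt <- countNuclei(sel, estimateMeanNucleusArea(sel, cfg), cfg)
    if (verbose) {
      a <- res@assessment
      message(sprintf(
        "%s: background=%s area1=%g area2=%g ratio=%.4g macro=%s objects=%d nuclei=%d",
        imageIds[[i]], a@backgroundClass, a@area1, a@area2, a@ratio,
        res@macroUsed, nObjects(sel), cnt@estimatedNuclei))
    }
    rows[[i]] <- data.frame(
      image_id = imageIds[[i]], macro_used = res@macroUsed,
      n_objects = nObjects(sel),
      total_object_area = sum(sel@features$area),
      estimated_nuclei = cnt@estimatedNuclei, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(
    image_id = character(0), macro_used = character(0),
    n_objects = integer(0), total_object_area = numeric(0),
    estimated_nuclei = integer(0), stringsAsFactors = FALSE)
  .checkCountTable(tab)
  tab
}
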