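# Stain palettes used by the generator. Each nucleus class is drawn flat
# with a color sampled inside a sub-box of the corresponding default
# segmentation range, so palette containment holds exactly (no
# anti-aliasing). Background strands have a light-brown core inside the
# light positive range (the color-overlap problem the procedure exists
# for) and a pale fringe inside bg2 but outside bg1 (the diffuse
# background indicator). The tissue base is near-white, outside every
# range.
.PALETTES <- list(
  POS_DARK  = list(lo = c(55, 35, 10),   hi = c(105, 75, 55)),
  POS_MID   = list(lo = c(130, 90, 50),  hi = c(160, 120, 90)),
  POS_LIGHT = list(lo = c(180, 128, 78), hi = c(210, 162, 128)),
  NEG       = list(lo = c(75, 85, 145),  hi = c(145, 155, 215)),
  BG_CORE   = list(lo = c(180, 128, 80), hi = c(210, 162, 130)),
  BG_PALE   = list(lo = c(218, 172, 137), hi = c(228, 183, 148)))
.BASE_LO <- 240L
.BASE_HI <- 255L

# geometry of the synthetic nuclei: mean radius band chosen so that the
# single-nucleus area spread stays inside the cluster-splitting band
# (max/min area < clusterFactor = 1.5); axes remain within [8, 16] px
.R_MEAN <- c(10.5, 12.5)
.ASPECT <- c(0.8, 1.25)

.samplePaletteColor <- function(class) {
  p <- .PALETTES[[class]]
  as.integer(round(runif(3, p$lo, p$hi)))
}

.coverageOf <- function(level) switch(level, low = 0.03, high = 0.12)
.paleFracOf <- function(level) switch(level, low = 0.10, high = 0.50)

#' Generate a synthetic IHC scene with ground truth
#'
#' Renders an IHC-like RGB image: a jittered near-white tissue base,
#' elliptical nuclei (DAB-brown positives split ~40/40/20% into dark, mid
#' and light; hematoxylin-blue negatives) and, for `backgroundLevel` low or
#' high, diffuse spurious-stain strands built from Gaussian bumps stamped
#' along random walks. Strand cores are light brown (inside the light
#' positive range, emulating the color overlap between background and
#' positive nuclei) and their fringes are pale brown (inside the `bg2`
#' diffuse-background indicator range); strands are large and irregular,
#' unlike the compact nuclei. Coverage is ~3% of the image at low and ~12%
#' at high level, with the pale fraction rising from 0.1 to 0.5.
#'
#' A fraction `overlapFraction` of the positive nuclei is placed in
#' touching chains of 2-4 (clusters); every chain member counts in the
#' ground truth. All randomness derives from `seed`: the same seed yields a
#' bit-identical scene, and the nucleus layout is shared across background
#' levels of the same seed (separate derived RNG streams), so background
#' effects can be compared per seed.
#'
#' @param nPositive,nNegative numbers of positive and negative nuclei.
#' @param backgroundLevel "none", "low" or "high".
#' @param overlapFraction fraction of positives placed in touching chains,
#'   in [0, 1].
#' @param width,height canvas in px (>= 64); the default 696 x 520 is half
#'   the 1392 x 1040 capture format on each side.
#' @param seed integer seed.
#' @return a [SyntheticScene-class].
#' @examples
#' scn <- generateScene(nPositive = 20, nNegative = 10, seed = 1)
#' sceneGroundTruth(scn)  # 20
#' @export
generateScene <- function(nPositive, nNegative = 0,
                          backgroundLevel = c("none", "low", "high"),
                          overlapFraction = 0, width = 696, height = 520,
                          seed = 1) {
  backgroundLevel <- match.arg(backgroundLevel)
  stopifnot(nPositive >= 0, nNegative >= 0,
            overlapFraction >= 0, overlapFraction <= 1,
            width >= 64, height >= 64)
  seed <- as.integer(seed)
  H <- as.integer(height); W <- as.integer(width)

  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(oldSeed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", oldSeed, envir = globalenv())
  })

  # stream A: tissue base + nucleus geometry, placement and colors
  set.seed(seed)
  img <- array(sample(.BASE_LO:.BASE_HI, H * W * 3L, replace = TRUE),
               dim = c(H, W, 3L))
  nuclei <- .placeNuclei(nPositive, nNegative, overlapFraction, H, W)

  # stream B: background strands (independent of the nucleus stream so the
  # same seed gives the same nucleus layout at every background level)
  blob <- matrix(FALSE, H, W)
  if (backgroundLevel != "none") {
    set.seed((seed %% 1000000000L) + 1000003L)
    field <- .strandField(H, W)
    cov <- .coverageOf(backgroundLevel)
    thr <- quantile(field, 1 - cov, names = FALSE)
    blob <- field > thr
    paleFrac <- .paleFracOf(backgroundLevel)
    coreThr <- quantile(field[blob], paleFrac, names = FALSE)
    core <- blob & (field >= coreThr)
    pale <- blob & !core
    for (ch in 1:3) {
      plane <- img[, , ch]
      p <- .PALETTES$BG_CORE
      plane[core] <- sample(p$lo[ch]:p$hi[ch], sum(core), replace = TRUE)
      p <- .PALETTES$BG_PALE
      plane[pale] <- sample(p$lo[ch]:p$hi[ch], sum(pale), replace = TRUE)
      img[, , ch] <- plane
    }
  }

  nucMask <- matrix(FALSE, H, W)
  if (nrow(nuclei) > 0) {
    pxList <- lapply(seq_len(nrow(nuclei)), function(i)
      .ellipsePixels(nuclei$centerRow[i], nuclei$centerCol[i],
                     nuclei$a[i], nuclei$b[i], nuclei$theta[i], H, W))
    nPx <- lengths(pxList)
    allPx <- unlist(pxList, use.names = FALSE)
    colCols <- c("colR", "colG", "colB")
    for (ch in 1:3) {
      plane <- img[, , ch]
      # chain members may overlap; later nuclei win (last assignment)
      plane[allPx] <- rep(nuclei[[colCols[ch]]], nPx)
      img[, , ch] <- plane
    }
    nucMask[allPx] <- TRUE
  }

  new("SyntheticScene", image = img, nuclei = nuclei,
      backgroundLevel = backgroundLevel,
      backgroundPixels = blob & !nucMask, seed = seed)
}

# smooth intensity field: Gaussian bumps stamped along drifting random walks
.strandField <- function(H, W) {
  field <- matrix(0, H, W)
  nStrands <- max(2L, as.integer(round(H * W / 45000)))
  for (s in seq_len(nStrands)) {
    sigma <- runif(1, 3.5, 5)
    steps <- sample(100:160, 1)
    pr <- runif(1, 1, H); pc <- runif(1, 1, W)
    dir <- runif(1, 0, 2 * pi)
    wrad <- ceiling(3 * sigma)
    for (k in seq_len(steps)) {
      # low direction noise keeps strands elongated (diffuse smears, not
      # nucleus-like beads)
      dir <- dir + rnorm(1, 0, 0.15)
      pr <- pr + 3 * sin(dir); pc <- pc + 3 * cos(dir)
      if (pr < 1) { pr <- 2 - pr; dir <- -dir }
      if (pr > H) { pr <- 2 * H - pr; dir <- -dir }
      if (pc < 1) { pc <- 2 - pc; dir <- pi - dir }
      if (pc > W) { pc <- 2 * W - pc; dir <- pi - dir }
      r0 <- max(1L, floor(pr - wrad)); r1 <- min(H, ceiling(pr + wrad))
      c0 <- max(1L, floor(pc - wrad)); c1 <- min(W, ceiling(pc + wrad))
      dr2 <- ((r0:r1) - pr)^2
      dc2 <- ((c0:c1) - pc)^2
      field[r0:r1, c0:c1] <- field[r0:r1, c0:c1] +
        exp(-outer(dr2, dc2, `+`) / (2 * sigma^2))
    }
  }
  field
}

.ellipsePixels <- function(cr, cc, a, b, theta, H, W) {
  e <- ceiling(max(a, b)) + 1L
  r0 <- max(1L, floor(cr - e)); r1 <- min(H, ceiling(cr + e))
  c0 <- max(1L, floor(cc - e)); c1 <- min(W, ceiling(cc + e))
  dr <- (r0:r1) - cr
  dc <- (c0:c1) - cc
  u <- (outer(dr, dc * 0, `+`) * cos(theta) + outer(dr * 0, dc, `+`) * sin(theta)) / a
  v <- (-outer(dr, dc * 0, `+`) * sin(theta) + outer(dr * 0, dc, `+`) * cos(theta)) / b
  inside <- u^2 + v^2 <= 1
  loc <- which(inside, arr.ind = TRUE)
  (c0 + loc[, 2] - 2L) * H + (r0 + loc[, 1] - 1L)
}

.placeNuclei <- function(nPositive, nNegative, overlapFraction, H, W) {
  cols <- c("centerRow", "centerCol", "a", "b", "theta", "class",
            "colR", "colG", "colB", "chain")
  empty <- data.frame(centerRow = numeric(0), centerCol = numeric(0),
                      a = numeric(0), b = numeric(0), theta = numeric(0),
                      class = character(0), colR = integer(0),
                      colG = integer(0), colB = integer(0),
                      chain = integer(0), stringsAsFactors = FALSE)
  total <- nPositive + nNegative
  if (total == 0) return(empty)

  posClasses <- if (nPositive > 0)
    sample(c("POS_DARK", "POS_MID", "POS_LIGHT"), nPositive, replace = TRUE,
           prob = c(0.4, 0.4, 0.2)) else character(0)

  # chain layout: overlapFraction of the positives in touching chains of 2-4
  nClustered <- round(overlapFraction * nPositive)
  chainSizes <- integer(0)
  rem <- nClustered
  while (rem >= 2) {
    s <- min(sample(2:4, 1), rem)
    chainSizes <- c(chainSizes, s)
    rem <- rem - s
  }
  nSingles <- nPositive - sum(chainSizes)

  geom <- function(n) {
    r <- runif(n, .R_MEAN[1], .R_MEAN[2])
    aspect <- runif(n, .ASPECT[1], .ASPECT[2])
    data.frame(a = r * sqrt(aspect), b = r / sqrt(aspect),
               theta = runif(n, 0, pi))
  }
  g <- geom(total)
  rmax <- pmax(g$a, g$b)
  classes <- c(posClasses, rep("NEG", nNegative))
  colMat <- t(vapply(classes, .samplePaletteColor, integer(3)))

  placedR <- numeric(0); placedC <- numeric(0); placedRad <- numeric(0)
  sep <- 3  # px clearance between non-chain neighbors (> sqrt(2) + raster slack)

  tryPlaceSingle <- function(rad) {
    for (t in 1:1000) {
      pr <- runif(1, rad + 2, H - rad - 1)
      pc <- runif(1, rad + 2, W - rad - 1)
      if (length(placedR) == 0 ||
          all(sqrt((placedR - pr)^2 + (placedC - pc)^2) >=
              placedRad + rad + sep))
        return(c(pr, pc))
    }
    # dense canvas: scan a jittered grid for any remaining feasible spot
    gr <- seq(rad + 2, H - rad - 1, by = 3)
    gc <- seq(rad + 2, W - rad - 1, by = 3)
    cand <- cbind(rep(gr, times = length(gc)) + runif(1, -1, 1),
                  rep(gc, each = length(gr)) + runif(1, -1, 1))
    ok <- rep(TRUE, nrow(cand))
    for (k in seq_along(placedR)) {
      ok <- ok & (cand[, 1] - placedR[k])^2 + (cand[, 2] - placedC[k])^2 >=
        (placedRad[k] + rad + sep)^2
      if (!any(ok)) return(NULL)
    }
    feasible <- which(ok)
    cand[feasible[sample.int(length(feasible), 1)], ]
  }

  # assignment order: chain members first, then single positives, negatives
  order <- integer(0)
  chainId <- integer(total)
  k <- 0L
  cid <- 0L
  for (s in chainSizes) {
    cid <- cid + 1L
    idx <- (k + 1L):(k + s)
    chainId[idx] <- cid
    order <- c(order, idx)
    k <- k + s
  }
  rest <- setdiff(seq_len(total), order)
  order <- c(order, rest)

  centerR <- rep(NA_real_, total); centerC <- rep(NA_real_, total)
  i <- 1L
  while (i <= length(order)) {
    id <- order[i]
    if (chainId[id] == 0L) {
      pos <- tryPlaceSingle(rmax[id])
      if (is.null(pos)) stop("infeasible packing: too many nuclei for the canvas",
                             call. = FALSE)
      centerR[id] <- pos[1]; centerC[id] <- pos[2]
      placedR <- c(placedR, pos[1]); placedC <- c(placedC, pos[2])
      placedRad <- c(placedRad, rmax[id])
      i <- i + 1L
    } else {
      # place a whole chain; restart the chain on a dead end
      cid <- chainId[id]
      members <- which(chainId == cid)
      placedOk <- FALSE
      for (attempt in 1:50) {
        mR <- numeric(0); mC <- numeric(0)
        ok <- TRUE
        for (j in seq_along(members)) {
          m <- members[j]
          if (j == 1) {
            pos <- tryPlaceSingle(rmax[m] + sum(rmax[members]) * 0.6)
            if (is.null(pos)) { ok <- FALSE; break }
          } else {
            prev <- members[j - 1]
            found <- FALSE
            for (t in 1:200) {
              phi <- runif(1, 0, 2 * pi)
              dst <- (rmax[prev] + rmax[m]) * runif(1, 0.75, 0.95)
              pr <- mR[j - 1] + dst * sin(phi)
              pc <- mC[j - 1] + dst * cos(phi)
              if (pr < rmax[m] + 2 || pr > H - rmax[m] - 1 ||
                  pc < rmax[m] + 2 || pc > W - rmax[m] - 1) next
              distOther <- sqrt((placedR - pr)^2 + (placedC - pc)^2)
              if (length(distOther) > 0 &&
                  any(distOther < placedRad + rmax[m] + sep)) next
              if (j > 2) {
                dPrev <- sqrt((mR[1:(j - 2)] - pr)^2 + (mC[1:(j - 2)] - pc)^2)
                if (any(dPrev < 2)) next  # avoid stacking on earlier members
              }
              found <- TRUE
              pos <- c(pr, pc)
              break
            }
            if (!found) { ok <- FALSE; break }
          }
          mR <- c(mR, pos[1]); mC <- c(mC, pos[2])
        }
        if (ok) { placedOk <- TRUE; break }
      }
      if (!placedOk)
        stop("infeasible packing: could not place nucleus cluster",
             call. = FALSE)
      centerR[members] <- mR; centerC[members] <- mC
      placedR <- c(placedR, mR); placedC <- c(placedC, mC)
      placedRad <- c(placedRad, rmax[members])
      i <- i + length(members)
    }
  }

  data.frame(centerRow = centerR, centerCol = centerC, a = g$a, b = g$b,
             theta = g$theta, class = classes,
             colR = colMat[, 1], colG = colMat[, 2], colB = colMat[, 3],
             chain = chainId, stringsAsFactors = FALSE)
}

#' Ground-truth positive count of a synthetic scene
#'
#' The number of positive (DAB-brown) nuclei rendered into the scene,
#' standing in for the gold-standard manual count when validating the
#' automated procedure on synthetic data.
#'
#' @param scene a [SyntheticScene-class].
#' @return integer(1).
#' @export
sceneGroundTruth <- function(scene) {
  stopifnot(is(scene, "SyntheticScene"))
  sum(scene@nuclei$class != "NEG")
}

#' Simulate a batch of scenes to disk
#'
#' Writes `scene_###.png` (or `.tif`) images plus a `ground_truth.csv`
#' (columns `image_id`, `n_positive`, `n_negative`, `background_level`,
#' `seed`) to a directory. Scene i uses seed `seed + i - 1`.
#'
#' @param nImages number of scenes.
#' @param outDir output directory (created if missing).
#' @param backgroundLevel "none", "low" or "high".
#' @param nPositive,nNegative nuclei per scene.
#' @param overlapFraction fraction of positives in touching chains.
#' @param width,height canvas in px.
#' @param seed base seed.
#' @param format "png" or "tiff".
#' @return the ground-truth data.frame, invisibly.
#' @export
simulateScenes <- function(nImages, outDir, backgroundLevel = "none",
                           nPositive = 50, nNegative = 25,
                           overlapFraction = 0.15, width = 696, height = 520,
                           seed = 1, format = c("png", "tiff")) {
  format <- match.arg(format)
  ext <- if (format == "png") "png" else "tif"
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  rows <- vector("list", nImages)
  for (i in seq_len(nImages)) {
    s <- seed + i - 1L
    scn <- generateScene(nPositive, nNegative, backgroundLevel,
                         overlapFraction, width, height, s)
    id <- sprintf("scene_%03d", i)
    writeRGBImage(scn@image, file.path(outDir, paste0(id, ".", ext)))
    rows[[i]] <- data.frame(image_id = id, n_positive = nPositive,
                            n_negative = nNegative,
                            background_level = backgroundLevel, seed = s,
                            stringsAsFactors = FALSE)
  }
  gt <- do.call(rbind, rows)
  write.csv(gt, file.path(outDir, "ground_truth.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(gt)
}
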