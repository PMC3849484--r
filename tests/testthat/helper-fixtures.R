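# shared fixtures: small images and brute-force oracles built in code

# uniform RGB image
uniformImage <- function(h, w, col) {
  array(rep(as.integer(col), each = h * w), dim = c(h, w, 3L))
}

# random RGB image
randomImage <- function(h, w) {
  array(sample(0:255, h * w * 3L, replace = TRUE), dim = c(h, w, 3L))
}

# paint a filled disc into an image, return the modified image
paintDisc <- function(img, row, col, radius, color) {
  H <- dim(img)[1]; W <- dim(img)[2]
  for (i in max(1, row - radius):min(H, row + radius))
    for (j in max(1, col - radius):min(W, col + radius))
      if ((i - row)^2 + (j - col)^2 <= radius^2)
        img[i, j, ] <- as.integer(color)
  img
}

discMask <- function(h, w, row, col, radius) {
  m <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    if ((i - row)^2 + (j - col)^2 <= radius^2) m[i, j] <- TRUE
  m
}

# exhaustive per-pixel color segmentation oracle
bruteSegment <- function(img, lo, hi) {
  H <- dim(img)[1]; W <- dim(img)[2]
  out <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    px <- img[i, j, ]
    out[i, j] <- all(px >= lo) && all(px <= hi)
  }
  out
}

# queue-based flood fill oracle for 8-connected component counting
floodComponents <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  comps <- list()
  for (i0 in seq_len(H)) for (j0 in seq_len(W)) {
    if (!mask[i0, j0] || seen[i0, j0]) next
    queue <- list(c(i0, j0)); seen[i0, j0] <- TRUE
    px <- integer(0)
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      px <- c(px, (p[2] - 1L) * H + p[1])
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
            mask[ni, nj] && !seen[ni, nj]) {
          seen[ni, nj] <- TRUE
          queue <- c(queue, list(c(ni, nj)))
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(px)
  }
  comps
}

# random blob mask: union of a few discs at random positions
randomBlobMask <- function(h, w, nBlobs = 5, rMax = 6) {
  m <- matrix(FALSE, h, w)
  for (k in seq_len(nBlobs)) {
    r <- sample(1:rMax, 1)
    m <- m | discMask(h, w, sample(seq_len(h), 1), sample(seq_len(w), 1), r)
  }
  m
}

defaultCfg <- ihcquant::defaultConfig()
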