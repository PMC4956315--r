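#' Disk structuring element
#'
#' Binary footprint containing every integer offset (dx, dy) with
#' dx^2 + dy^2 <= radius^2, the disk used by the opening and closing
#' operators. The default radius of 8 pixels matches the widest vessel
#' caliber the method is tuned for (vessel widths of 1--8 px in DRIVE and
#' STARE resolution).
#'
#' @param radius integer radius in pixels, >= 1.
#' @return a (2r+1) x (2r+1) 0/1 matrix with the disk footprint.
#' @export
disk_se <- function(radius = 8) {
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1)
    vseg_error("structuring-element radius must be a positive integer",
               "vseg_bad_input")
  d <- -radius:radius
  k <- outer(d^2, d^2, "+") <= radius^2
  structure(k * 1, radius = radius)
}

se_radius <- function(se) {
  r <- attr(se, "radius")
  if (is.null(r)) r <- (nrow(se) - 1L) %/% 2L
  as.integer(r)
}

# Shared driver for grayscale erosion/dilation: reflect-pad so border
# handling is symmetric, then sliding min/max over the footprint.
morph_apply <- function(img, se, op = c("erode", "dilate")) {
  assert_gray(img)
  op <- match.arg(op)
  r <- se_radius(se)
  p <- pad_reflect(img, r)
  out <- if (op == "erode") EBImage::erode(p, se) else EBImage::dilate(p, se)
  out[(r + 1):(r + nrow(img)), (r + 1):(r + ncol(img)), drop = FALSE]
}

#' Grayscale morphological opening
#'
#' Erosion followed by dilation with the same structuring element. Opening
#' removes bright structures narrower than the footprint; it is
#' anti-extensive (output <= input) and idempotent.
#'
#' @param img gray matrix.
#' @param se structuring element from [disk_se()].
#' @return gray matrix of the same shape.
#' @export
morph_open <- function(img, se = disk_se(8)) {
  morph_apply(morph_apply(img, se, "erode"), se, "dilate")
}

#' Grayscale morphological closing
#'
#' Dilation followed by erosion; fills dark structures narrower than the
#' footprint. Extensive (output >= input) and idempotent.
#'
#' @inheritParams morph_open
#' @return gray matrix of the same shape.
#' @export
morph_close <- function(img, se = disk_se(8)) {
  morph_apply(morph_apply(img, se, "dilate"), se, "erode")
}

#' Modified top-hat transform
#'
#' Background removal step `I - open(close(I))`: the closing first fills
#' dark gaps thinner than the footprint so that the subsequent opening
#' estimates the background more robustly than the plain white top-hat
#' `I - open(I)`. With disk radius 8 every vessel (width 1--8 px, presented
#' bright after complementing the green channel) is removed from the
#' background estimate and therefore survives the subtraction.
#'
#' Negative values of the raw difference are clipped to zero, and the result
#' is min-max rescaled to \[0,1\] when its maximum is positive.
#'
#' @param img gray matrix with vessels bright (complement the CLAHE output
#'   first; see [segment_vessels()]).
#' @param se_close,se_open structuring elements for the closing and opening;
#'   both default to a disk of radius 8.
#' @param rescale if `FALSE`, return the clipped difference without min-max
#'   rescaling (used by oracle tests).
#' @return gray matrix in \[0,1\].
#' @export
modified_top_hat <- function(img, se_close = disk_se(8), se_open = disk_se(8),
                             rescale = TRUE) {
  assert_gray(img)
  bg <- morph_open(morph_close(img, se_close), se_open)
  th <- pmax(img - bg, 0)
  if (rescale && max(th) > 1e-12) th <- th / max(th)
  th
}

#' Complement a gray image
#'
#' Maps v to 1 - v. Vessels are dark in the green channel; complementing
#' turns them into bright ridges, the polarity assumed by the top-hat and
#' Hessian stages.
#'
#' @param img gray matrix in \[0,1\].
#' @return complemented gray matrix.
#' @export
complement_image <- function(img) {
  assert_gray(img)
  1 - img
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Per-tile histogram equalization with the tile histogram clipped at
#' `clip_limit` times the tile pixel count and the excess redistributed
#' uniformly over all bins; pixel mappings are interpolated bilinearly
#' between the four nearest tile centers, which suppresses tile-boundary
#' artifacts. The clip limit bounds noise amplification in flat regions --
#' useful values for fundus images lie between 0 and 0.01 of the tile area.
#'
#' @param img gray matrix in \[0,1\].
#' @param clip_limit histogram clip as a fraction of the tile pixel count,
#'   in \[0, 0.01\]; at least one count per bin is always allowed.
#' @param tile_grid integer vector `c(rows, cols)` of contextual tiles.
#' @param nbins number of histogram bins.
#' @return equalized gray matrix in \[0,1\].
#' @export
clahe <- function(img, clip_limit = 0.01, tile_grid = c(8, 8), nbins = 256) {
  assert_gray(img)
  if (length(img) == 0) vseg_error("empty image", "vseg_bad_input")
  if (clip_limit < 0 || clip_limit > 0.01)
    vseg_error("clip_limit must lie in [0, 0.01]", "vseg_bad_input")
  tile_grid <- as.integer(tile_grid)
  if (length(tile_grid) != 2L || any(tile_grid < 1))
    vseg_error("tile_grid must be two positive integers", "vseg_bad_input")
  nr <- nrow(img); nc <- ncol(img)
  if (tile_grid[1] > nr || tile_grid[2] > nc)
    vseg_error("tile grid finer than the image: tiles would be empty",
               "vseg_tile_too_large")
  tr <- tile_grid[1]; tc <- tile_grid[2]

  bin <- matrix(as.integer(floor(clamp01(img) * (nbins - 1) + 0.5)), nr, nc)
  # Tile boundaries of near-equal size.
  rb <- floor(seq(0, nr, length.out = tr + 1))
  cb <- floor(seq(0, nc, length.out = tc + 1))
  maps <- array(0, c(tr, tc, nbins))
  rcent <- numeric(tr); ccent <- numeric(tc)
  for (i in seq_len(tr)) {
    for (j in seq_len(tc)) {
      rows <- (rb[i] + 1):rb[i + 1]
      cols <- (cb[j] + 1):cb[j + 1]
      maps[i, j, ] <- clahe_tile_map(bin[rows, cols], nbins, clip_limit)
      rcent[i] <- (rb[i] + 1 + rb[i + 1]) / 2
      ccent[j] <- (cb[j] + 1 + cb[j + 1]) / 2
    }
  }
  # Bilinear interpolation between tile-center mappings, clamped at borders.
  ry <- interp_coords(seq_len(nr), rcent)
  cx <- interp_coords(seq_len(nc), ccent)
  i0 <- matrix(ry$i0, nr, nc); i1 <- matrix(ry$i1, nr, nc)
  wy <- matrix(ry$w,  nr, nc)
  j0 <- matrix(cx$i0, nr, nc, byrow = TRUE); j1 <- matrix(cx$i1, nr, nc, byrow = TRUE)
  wx <- matrix(cx$w,  nr, nc, byrow = TRUE)
  b1 <- bin + 1L
  out <- (1 - wy) * (1 - wx) * maps[cbind(c(i0), c(j0), c(b1))] +
         (1 - wy) * wx       * maps[cbind(c(i0), c(j1), c(b1))] +
         wy       * (1 - wx) * maps[cbind(c(i1), c(j0), c(b1))] +
         wy       * wx       * maps[cbind(c(i1), c(j1), c(b1))]
  matrix(clamp01(out), nr, nc)
}

# Equalization mapping of one tile: clipped histogram -> cdf on [0,1].
clahe_tile_map <- function(bins, nbins, clip_limit) {
  n <- length(bins)
  h <- tabulate(as.integer(bins) + 1L, nbins)
  cl <- max(clip_limit * n, 1)
  excess <- sum(pmax(h - cl, 0))
  h <- pmin(h, cl) + excess / nbins
  cumsum(h) / n
}

# For each query coordinate, bracketing center indices and the weight of
# the upper one; weights collapse to the nearest center outside the span.
interp_coords <- function(q, centers) {
  k <- length(centers)
  i0 <- findInterval(q, centers)
  i0 <- pmin(pmax(i0, 1L), max(k - 1L, 1L))
  i1 <- pmin(i0 + 1L, k)
  denom <- centers[i1] - centers[i0]
  w <- ifelse(denom > 0, (q - centers[i0]) / denom, 0)
  list(i0 = i0, i1 = i1, w = pmin(pmax(w, 0), 1))
}
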