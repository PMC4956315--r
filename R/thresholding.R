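# Otsu's criterion in its variance-ratio form, the wide/thin fusion step,
# and the two-valued region-based threshold map that classifies vessels.

#' Build an intensity histogram over the field of view
#'
#' Quantizes intensities in \[0,1\] to `L` levels by
#' `floor(v * (L - 1) + 0.5)` and counts only pixels inside the FOV mask.
#'
#' @param img gray matrix in \[0,1\].
#' @param fov 0/1 matrix; must contain at least one pixel. Use
#'   `matrix(1L, nrow(img), ncol(img))` to histogram the full frame.
#' @param L number of gray levels (default 256).
#' @return object of class `gray_histogram`: integer `counts` (length `L`),
#'   probabilities `p`, levels `L`, total count `n`.
#' @export
build_histogram <- function(img, fov, L = 256) {
  assert_gray(img)
  assert_mask(fov, "fov")
  assert_same_shape(img, fov, "img/fov")
  if (L < 2) vseg_error("L must be >= 2", "vseg_bad_input")
  v <- img[fov == 1]
  if (length(v) == 0) vseg_error("empty FOV: no pixels to histogram",
                                 "vseg_empty_fov")
  lev <- as.integer(floor(clamp01(v) * (L - 1) + 0.5))
  counts <- tabulate(lev + 1L, nbins = L)
  structure(list(counts = counts, p = counts / sum(counts),
                 L = as.integer(L), n = sum(counts)),
            class = "gray_histogram")
}

#' Otsu's optimal threshold and class-variance statistics
#'
#' Evaluates every candidate split t in 0..L-2 between classes
#' S0 = {0..t} and S1 = {t+1..L-1} and returns the t maximizing the
#' between-class variance sigma2_B (equivalently the ratio
#' alpha = sigma2_B / sigma2_W, since the total variance is fixed).
#' Ties are broken toward the smallest level so the output is
#' deterministic.
#'
#' @param hist a `gray_histogram`.
#' @return list with `t_star` (integer level), `threshold` (the same level
#'   mapped back to intensity, t_star / (L-1)) and `stats`, an `otsu_stats`
#'   object holding omega0/1, mu0/1, mu_t, muT, sigma2_W/B/T and the ratios
#'   alpha, beta, gamma at the optimum.
#' @export
otsu_threshold <- function(hist) {
  stopifnot(inherits(hist, "gray_histogram"))
  p <- hist$p
  L <- hist$L
  if (sum(p > 0) < 2)
    vseg_error("degenerate histogram: fewer than two populated levels",
               "vseg_degenerate_histogram")
  i <- 0:(L - 1)
  muT <- sum(i * p)
  sigma2_T <- sum((i - muT)^2 * p)
  om0 <- cumsum(p)[1:(L - 1)]          # omega0 at t = 0..L-2
  mut <- cumsum(i * p)[1:(L - 1)]      # first moment of S0
  om1 <- 1 - om0
  mu0 <- ifelse(om0 > 0, mut / om0, 0)
  mu1 <- ifelse(om1 > 0, (muT - mut) / om1, 0)
  s2b <- ifelse(om0 > 0 & om1 > 0,
                om0 * (mu0 - muT)^2 + om1 * (mu1 - muT)^2, 0)
  t_star <- which.max(s2b) - 1L        # which.max takes the first maximum
  # Class variances at the optimum (within-class variance, Eq 14 form).
  s0 <- i <= t_star
  w0 <- om0[t_star + 1L]; w1 <- om1[t_star + 1L]
  m0 <- mu0[t_star + 1L]; m1 <- mu1[t_star + 1L]
  var0 <- if (w0 > 0) sum((i[s0] - m0)^2 * p[s0]) / w0 else 0
  var1 <- if (w1 > 0) sum((i[!s0] - m1)^2 * p[!s0]) / w1 else 0
  sigma2_W <- w0 * var0 + w1 * var1
  sigma2_B <- s2b[t_star + 1L]
  stats <- structure(list(
    omega0 = w0, omega1 = w1, mu0 = m0, mu1 = m1,
    mu_t = mut[t_star + 1L], muT = muT,
    sigma2_W = sigma2_W, sigma2_B = sigma2_B, sigma2_T = sigma2_T,
    alpha = if (sigma2_W > 0) sigma2_B / sigma2_W else Inf,
    beta = if (sigma2_T > 0) sigma2_B / sigma2_T else NA_real_,
    gamma = if (sigma2_W > 0) sigma2_T / sigma2_W else Inf
  ), class = "otsu_stats")
  list(t_star = t_star, threshold = t_star / (L - 1), stats = stats)
}

#' Threshold an image into a binary mask
#'
#' Inclusive comparison: pixels with intensity >= t become 1. When a FOV
#' mask is given, pixels outside it are 0.
#'
#' @param img gray matrix.
#' @param t threshold intensity in \[0,1\].
#' @param fov optional 0/1 matrix.
#' @return integer 0/1 matrix.
#' @export
apply_threshold <- function(img, t, fov = NULL) {
  assert_gray(img)
  out <- (img >= t) * 1L
  if (!is.null(fov)) {
    assert_mask(fov, "fov")
    assert_same_shape(img, fov, "img/fov")
    out <- out * fov
  }
  out
}

#' Fuse the wide-vessel binary map into the thin-vessel enhanced image
#'
#' Sets the thin-vessel image to 1.0 wherever the wide-vessel mask is on
#' (pixel-wise maximum with the binary map). Wide vessels thus appear
#' saturated in the fused image and are guaranteed to survive any
#' subsequent threshold in \[0,1\].
#'
#' @param thin_img gray matrix (thin-scale vesselness).
#' @param wide_mask 0/1 matrix (global-Otsu wide-vessel map).
#' @return fused gray matrix.
#' @export
fuse_wide_into_thin <- function(thin_img, wide_mask) {
  assert_gray(thin_img)
  assert_mask(wide_mask, "wide_mask")
  assert_same_shape(thin_img, wide_mask, "thin_img/wide_mask")
  pmax(thin_img, wide_mask + 0)
}

#' Region-based threshold map around wide vessels
#'
#' Two-valued local threshold derived from the global Otsu level: inside
#' the neighborhood of wide vessels (the wide mask dilated by a disk of the
#' given radius) the threshold is raised by `offset` to suppress the noise
#' that clusters around strong vessels; away from them it is lowered by
#' `offset` so faint thin vessels are still captured. Values are clamped to
#' \[0,1\].
#'
#' @param t_global global threshold intensity in \[0,1\].
#' @param wide_mask 0/1 matrix of wide vessels.
#' @param offset nonnegative threshold increment (default 0.05).
#' @param radius disk radius in pixels defining the neighborhood
#'   (default 8); radius 0 means the wide mask itself.
#' @return object of class `threshold_map`: matrix `values` plus the
#'   `t_global`, `offset`, `radius` that built it.
#' @export
region_threshold_map <- function(t_global, wide_mask, offset = 0.05, radius = 8) {
  assert_mask(wide_mask, "wide_mask")
  if (offset < 0) vseg_error("offset must be >= 0", "vseg_bad_input")
  if (radius < 0) vseg_error("radius must be >= 0", "vseg_bad_input")
  nb <- if (radius >= 1 && any(wide_mask == 1L)) {
    (morph_apply(wide_mask + 0, disk_se(radius), "dilate") > 0.5) * 1L
  } else {
    wide_mask
  }
  vals <- ifelse(nb == 1L, clamp01(t_global + offset), clamp01(t_global - offset))
  structure(list(values = matrix(vals, nrow(wide_mask), ncol(wide_mask)),
                 t_global = t_global, offset = offset, radius = radius),
            class = "threshold_map")
}

#' Classify vessel pixels with the region threshold map
#'
#' A pixel is a vessel if it is in the wide mask or its fused intensity
#' meets the local threshold: `wide_mask | (fused >= tmap)`.
#'
#' @param fused gray matrix from [fuse_wide_into_thin()].
#' @param tmap a `threshold_map`.
#' @param wide_mask 0/1 matrix of wide vessels.
#' @return integer 0/1 matrix; always a superset of `wide_mask`.
#' @export
classify_pixels <- function(fused, tmap, wide_mask) {
  stopifnot(inherits(tmap, "threshold_map"))
  assert_gray(fused)
  assert_mask(wide_mask, "wide_mask")
  assert_same_shape(fused, tmap$values, "fused/threshold map")
  assert_same_shape(fused, wide_mask, "fused/wide_mask")
  ((wide_mask == 1L) | (fused >= tmap$values)) * 1L
}
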