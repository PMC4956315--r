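# Scale-space second-derivative analysis. A vessel is a ridge: one large
# curvature across the vessel, one near zero along it, so the eigenvalue
# difference lambda2 - lambda1 of the (scale-normalized) Hessian scores
# tubular structure while staying cheap -- no Frangi ratio terms.

# 1-D Gaussian-derivative taps at integer offsets -h..h, calibrated so that
# polynomial inputs reproduce their derivatives exactly under correlation:
# order 0: sum(k) = 1; order 1: sum(u*k) = 1; order 2: sum(k) = 0 and
# sum(u^2*k) = 2. Calibration removes the discretization bias of plain
# sampling, which matters at sigma ~ 1.
gauss_kernels <- function(sigma) {
  h <- ceiling(4 * sigma)
  u <- -h:h
  g0 <- exp(-u^2 / (2 * sigma^2))
  g0 <- g0 / sum(g0)
  g1 <- u * exp(-u^2 / (2 * sigma^2))
  g1 <- g1 / sum(u * g1)
  g2 <- (u^2 / sigma^2 - 1) * exp(-u^2 / (2 * sigma^2))
  g2 <- g2 - mean(g2)
  g2 <- g2 * (2 / sum(u^2 * g2))
  list(g0 = g0, g1 = g1, g2 = g2, halfwidth = h)
}

# Separable correlation with reflect padding; krow acts along rows (y),
# kcol along columns (x).
conv_sep <- function(img, krow, kcol) {
  hr <- (length(krow) - 1L) %/% 2L
  hc <- (length(kcol) - 1L) %/% 2L
  p <- pad_reflect(img, max(hr, hc))
  off <- max(hr, hc)
  nr <- nrow(img); nc <- ncol(img)
  tmp <- matrix(0, nr, ncol(p))
  for (t in seq_along(krow))
    tmp <- tmp + krow[t] * p[(off - hr + t - 1) + seq_len(nr), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (t in seq_along(kcol))
    out <- out + kcol[t] * tmp[, (off - hc + t - 1) + seq_len(nc), drop = FALSE]
  out
}

#' Gaussian second derivatives (Hessian field) of an image
#'
#' Convolves the image with the three second-order Gaussian-derivative
#' kernels at standard deviation `sigma` (kernel half-width `ceiling(4*sigma)`,
#' reflect padding), giving the per-pixel symmetric Hessian
#' \eqn{[h11, h12; h12, h22]} with x along columns and y along rows.
#'
#' @param img gray matrix.
#' @param sigma derivative scale in pixels, > 0.
#' @return an object of class `hessian_field`: list with matrices `h11`,
#'   `h12`, `h22` and the scalar `sigma`.
#' @export
gaussian_second_derivatives <- function(img, sigma) {
  assert_gray(img)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    vseg_error("sigma must be a positive scalar", "vseg_bad_sigma")
  k <- gauss_kernels(sigma)
  structure(list(
    h11 = conv_sep(img, k$g0, k$g2),
    h12 = conv_sep(img, k$g1, k$g1),
    h22 = conv_sep(img, k$g2, k$g0),
    sigma = sigma
  ), class = "hessian_field")
}

#' Scale-normalize a Hessian field
#'
#' Multiplies each second derivative by sigma^2 so that responses are
#' comparable across scales (a ridge of width w responds maximally near
#' sigma ~ w after normalization).
#'
#' @param h a `hessian_field`.
#' @return the normalized `hessian_field` (same sigma).
#' @export
scale_normalize <- function(h) {
  stopifnot(inherits(h, "hessian_field"))
  s2 <- h$sigma^2
  structure(list(h11 = s2 * h$h11, h12 = s2 * h$h12, h22 = s2 * h$h22,
                 sigma = h$sigma), class = "hessian_field")
}

#' Rotate a Hessian field into a new coordinate frame
#'
#' Applies the tensor rotation R H R^T per pixel for a frame rotated by
#' `theta`. Eigenvalues are invariant under this map, so the default
#' pipeline never needs it; it is provided (and tested) as the explicit
#' directional form of the operator.
#'
#' @param h a `hessian_field`.
#' @param theta rotation angle in radians.
#' @return the rotated `hessian_field`.
#' @export
rotate_hessian <- function(h, theta) {
  stopifnot(inherits(h, "hessian_field"))
  c2 <- cos(theta)^2; s2 <- sin(theta)^2; s2t <- sin(2 * theta); c2t <- cos(2 * theta)
  structure(list(
    h11 = h$h11 * c2 + h$h12 * s2t + h$h22 * s2,
    h12 = -0.5 * h$h11 * s2t + h$h12 * c2t + 0.5 * h$h22 * s2t,
    h22 = h$h11 * s2 - h$h12 * s2t + h$h22 * c2,
    sigma = h$sigma
  ), class = "hessian_field")
}

#' Eigenvalues of a Hessian field
#'
#' Per-pixel closed-form eigenvalues of the symmetric 2x2 Hessian,
#' \eqn{\lambda_{1,2} = ((h11+h22) \mp \sqrt{(h11-h22)^2 + 4 h12^2})/2}.
#'
#' @param h a `hessian_field`.
#' @param ordering `"algebraic"` (default, lambda1 <= lambda2) or
#'   `"magnitude"` (|lambda1| <= |lambda2|, Frangi-style). The algebraic
#'   ordering makes the difference lambda2 - lambda1 a nonnegative
#'   vesselness score.
#' @return an object of class `eigen_field`: matrices `lambda1`, `lambda2`
#'   plus `sigma` and the ordering used.
#' @export
eigen_decompose <- function(h, ordering = c("algebraic", "magnitude")) {
  stopifnot(inherits(h, "hessian_field"))
  ordering <- match.arg(ordering)
  tr <- h$h11 + h$h22
  disc <- sqrt((h$h11 - h$h22)^2 + 4 * h$h12^2)
  l1 <- (tr - disc) / 2
  l2 <- (tr + disc) / 2
  if (ordering == "magnitude") {
    swap <- abs(l1) > abs(l2)
    tmp <- l1[swap]; l1[swap] <- l2[swap]; l2[swap] <- tmp
  }
  structure(list(lambda1 = l1, lambda2 = l2, sigma = h$sigma,
                 ordering = ordering), class = "eigen_field")
}

#' Eigenvalue-difference vesselness
#'
#' The vesselness score lambda2 - lambda1, which for algebraic ordering
#' equals the discriminant \eqn{\sqrt{(h11-h22)^2 + 4 h12^2} \ge 0}:
#' isotropic neighborhoods score zero, tubular ones score high. Optionally
#' min-max rescaled to \[0,1\] over the field of view so that a fixed-range
#' histogram can be built on it.
#'
#' @param e an `eigen_field`.
#' @param fov optional 0/1 matrix restricting the rescale range.
#' @param rescale rescale to \[0,1\] (default `TRUE`).
#' @return gray matrix of vesselness scores.
#' @export
vesselness_difference <- function(e, fov = NULL, rescale = TRUE) {
  stopifnot(inherits(e, "eigen_field"))
  v <- e$lambda2 - e$lambda1
  if (rescale) v <- minmax_rescale(v, fov)
  v
}

#' Single-scale vessel enhancement
#'
#' Composition Gaussian second derivatives -> scale normalization ->
#' eigenvalues -> lambda2 - lambda1, applied to the top-hat output. Run at
#' sigma = 1 for the thin-vessel image and sigma = 2.5 for the wide-vessel
#' image.
#'
#' @param img gray matrix (top-hat output, vessels bright).
#' @param sigma scale in pixels.
#' @param fov optional 0/1 matrix; passed to [vesselness_difference()].
#' @param rescale min-max rescale to \[0,1\] (default). Use `FALSE` to keep
#'   raw sigma^2-normalized responses, which are directly comparable across
#'   scales (a per-scale min-max destroys that comparability).
#' @return gray vesselness matrix (in \[0,1\] when rescaled).
#' @export
enhance_at_scale <- function(img, sigma, fov = NULL, rescale = TRUE) {
  h <- scale_normalize(gaussian_second_derivatives(img, sigma))
  vesselness_difference(eigen_decompose(h), fov = fov, rescale = rescale)
}
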