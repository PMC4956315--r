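# Internal raster helpers shared across modules. All images are plain R
# matrices (gray, row-major, [0,1]) or h x w x 3 arrays (color); binary
# masks are integer 0/1 matrices.

vseg_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "vseg_error")))
}

assert_gray <- function(img, what = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    vseg_error(sprintf("`%s` must be a numeric matrix", what), "vseg_bad_input")
  invisible(img)
}

assert_mask <- function(mask, what = "mask") {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1)))
    vseg_error(sprintf("`%s` must be a 0/1 matrix", what), "vseg_bad_input")
  invisible(mask)
}

assert_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    vseg_error(sprintf("%s have mismatched shapes (%s vs %s)", what,
                       paste(dim(a)[1:2], collapse = "x"),
                       paste(dim(b)[1:2], collapse = "x")),
               "vseg_shape_mismatch")
  invisible(NULL)
}

is_color_image <- function(img) {
  is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' @keywords internal
#' @noRd
minmax_rescale <- function(img, mask = NULL) {
  v <- if (is.null(mask)) img else img[mask == 1]
  lo <- min(v)
  hi <- max(v)
  # a range at floating-point dust level is a flat image, not signal
  if (hi - lo <= 1e-12 * max(abs(hi), abs(lo), 1)) return(img * 0)
  clamp01((img - lo) / (hi - lo))
}

# Symmetric (half-sample) reflection padding by `p` pixels on every side.
pad_reflect <- function(m, p) {
  if (p == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (p > nr || p > nc)
    vseg_error("reflection pad wider than the image", "vseg_bad_input")
  ri <- c(p:1, 1:nr, nr:(nr - p + 1))
  ci <- c(p:1, 1:nc, nc:(nc - p + 1))
  m[ri, ci, drop = FALSE]
}

#' Round half away from zero at a fixed number of decimals
#'
#' Decimal rounding as used in printed results tables: ties go away from
#' zero (so 0.8605 at three decimals gives 0.861), unlike [round()]'s
#' round-half-even. A tiny epsilon guards against binary representation of
#' decimal ties falling just below .5.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals.
#' @examples
#' round_half_up(0.8605, 3)  # 0.861
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
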