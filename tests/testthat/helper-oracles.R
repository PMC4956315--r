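# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, direct formulas, base eigen().

# Symmetric reflection of an out-of-range index into 1..n.
reflect_idx <- function(i, n) {
  ifelse(i < 1L, 1L - i, ifelse(i > n, 2L * n + 1L - i, i))
}

disk_offsets <- function(radius) {
  d <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  d[d$dy^2 + d$dx^2 <= radius^2, ]
}

# Exhaustive sliding-window min/max morphology with reflected borders.
bf_morph <- function(img, radius, op) {
  off <- disk_offsets(radius)
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  f <- if (op == "erode") min else max
  for (r in seq_len(nr)) {
    rs <- reflect_idx(r + off$dy, nr)
    for (c in seq_len(nc)) {
      cs <- reflect_idx(c + off$dx, nc)
      out[r, c] <- f(img[cbind(rs, cs)])
    }
  }
  out
}

bf_open <- function(img, radius) bf_morph(bf_morph(img, radius, "erode"), radius, "dilate")
bf_close <- function(img, radius) bf_morph(bf_morph(img, radius, "dilate"), radius, "erode")

# Brute-force Otsu: expand the histogram to raw values and evaluate every
# split with direct class means; between-class variance in the
# omega0*omega1*(mu0-mu1)^2 form (algebraically equal to the class-scatter
# form the package uses, coded independently).
bf_otsu <- function(counts) {
  L <- length(counts)
  x <- rep(0:(L - 1), counts)
  n <- length(x)
  s2b <- vapply(0:(L - 2), function(t) {
    a <- x[x <= t]; b <- x[x > t]
    if (length(a) == 0 || length(b) == 0) return(0)
    w0 <- length(a) / n
    w0 * (1 - w0) * (mean(a) - mean(b))^2
  }, numeric(1))
  list(t_star = which.max(s2b) - 1L, s2b = s2b)
}

# Within/total variance of a split, direct definitions.
bf_class_variances <- function(counts, t) {
  L <- length(counts)
  x <- rep(0:(L - 1), counts)
  a <- x[x <= t]; b <- x[x > t]
  pvar <- function(v) if (length(v) == 0) 0 else mean((v - mean(v))^2)
  w0 <- length(a) / length(x)
  list(s2w = w0 * pvar(a) + (1 - w0) * pvar(b), s2t = pvar(x))
}

# Prepared-image path shared by enhancement-level tests: green channel with
# the aperture filled, CLAHE, complement, top-hat.
tophat_of_sample <- function(sample) {
  fov <- sample$fov
  inside <- fov == 1
  g <- sample$image[, , 2]
  g[!inside] <- mean(g[inside])
  cl <- clahe(g)
  cl[!inside] <- mean(cl[inside])
  modified_top_hat(complement_image(cl))
}

expect_rel_equal <- function(got, want, tol, scale_floor = 1e-8) {
  scale <- pmax(abs(want), scale_floor)
  expect_lt(max(abs(got - want) / scale), tol)
}
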