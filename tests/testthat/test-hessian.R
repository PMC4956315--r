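test_that("Gaussian second derivatives reproduce derivatives of polynomials", {
  n <- 41
  xs <- matrix(rep(0:(n - 1), each = n), n, n)   # x along columns
  ys <- matrix(rep(0:(n - 1), times = n), n, n)  # y along rows
  interior <- function(m) m[13:29, 13:29]
  for (sigma in c(1, 2.5)) {
    hf <- gaussian_second_derivatives(xs^2 / 2, sigma)
    expect_lt(max(abs(interior(hf$h11) - 1)), 1e-3)
    expect_lt(max(abs(interior(hf$h22))), 1e-3)
    expect_lt(max(abs(interior(hf$h12))), 1e-3)

    hf <- gaussian_second_derivatives(ys^2 / 2, sigma)
    expect_lt(max(abs(interior(hf$h22) - 1)), 1e-3)
    expect_lt(max(abs(interior(hf$h11))), 1e-3)

    hf <- gaussian_second_derivatives(xs * ys, sigma)
    expect_lt(max(abs(interior(hf$h12) - 1)), 1e-3)
    expect_lt(max(abs(interior(hf$h11))), 1e-3)
    expect_lt(max(abs(interior(hf$h22))), 1e-3)
  }
  flat <- gaussian_second_derivatives(matrix(0.7, 21, 21), 1.5)
  expect_lt(max(abs(flat$h11), abs(flat$h12), abs(flat$h22)), 1e-12)
  expect_error(gaussian_second_derivatives(matrix(0, 4, 4), 0),
               class = "vseg_bad_sigma")
})

test_that("scale normalization multiplies by sigma^2 and preserves sigma", {
  h <- structure(list(h11 = matrix(0.4, 2, 2), h12 = matrix(-0.2, 2, 2),
                      h22 = matrix(1, 2, 2), sigma = 2.5),
                 class = "hessian_field")
  hn <- scale_normalize(h)
  expect_equal(hn$h11, matrix(2.5, 2, 2))
  expect_equal(hn$h12, matrix(-1.25, 2, 2))
  expect_equal(hn$sigma, 2.5)
  h1 <- structure(list(h11 = matrix(1), h12 = matrix(2), h22 = matrix(3),
                       sigma = 1), class = "hessian_field")
  expect_equal(scale_normalize(h1), h1)
})

test_that("eigen decomposition matches closed forms and base eigen()", {
  mk <- function(a, b, c) structure(list(h11 = matrix(a), h12 = matrix(b),
                                         h22 = matrix(c), sigma = 1),
                                    class = "hessian_field")
  e <- eigen_decompose(mk(-4, 0, 0))
  expect_equal(c(e$lambda1, e$lambda2), c(-4, 0))
  e <- eigen_decompose(mk(2, 1, 2))
  expect_equal(c(e$lambda1, e$lambda2), c(1, 3))
  e <- eigen_decompose(mk(0.3, 0, 0.3))
  expect_equal(c(e$lambda1, e$lambda2), c(0.3, 0.3))

  set.seed(21)
  for (i in 1:50) {
    a <- rnorm(1); b <- rnorm(1); c <- rnorm(1)
    e <- eigen_decompose(mk(a, b, c))
    want <- sort(eigen(matrix(c(a, b, b, c), 2, 2), symmetric = TRUE)$values)
    expect_rel_equal(c(e$lambda1, e$lambda2), want, 1e-9)
  }
})

test_that("eigenvalues are invariant under Hessian rotation", {
  set.seed(22)
  n <- 1000
  h <- structure(list(h11 = matrix(rnorm(n), n, 1), h12 = matrix(rnorm(n), n, 1),
                      h22 = matrix(rnorm(n), n, 1), sigma = 1),
                 class = "hessian_field")
  e0 <- eigen_decompose(h)
  for (theta in seq(0, 2 * pi, length.out = 8)) {
    er <- eigen_decompose(rotate_hessian(h, theta))
    expect_rel_equal(er$lambda1, e0$lambda1, 1e-9)
    expect_rel_equal(er$lambda2, e0$lambda2, 1e-9)
  }
  # trace and determinant conservation
  expect_rel_equal(e0$lambda1 + e0$lambda2, h$h11 + h$h22, 1e-9)
  expect_rel_equal(e0$lambda1 * e0$lambda2, h$h11 * h$h22 - h$h12^2, 1e-9)
})

test_that("rotate_hessian agrees with the explicit R H R^T matrix oracle", {
  set.seed(23)
  for (i in 1:50) {
    a <- rnorm(1); b <- rnorm(1); c <- rnorm(1); theta <- runif(1, 0, 2 * pi)
    h <- structure(list(h11 = matrix(a), h12 = matrix(b), h22 = matrix(c),
                        sigma = 1), class = "hessian_field")
    hr <- rotate_hessian(h, theta)
    R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
    M <- R %*% matrix(c(a, b, b, c), 2, 2) %*% t(R)
    expect_equal(c(hr$h11, hr$h12, hr$h22), c(M[1, 1], M[1, 2], M[2, 2]),
                 tolerance = 1e-12)
  }
  # special angles read off the formulas
  h <- structure(list(h11 = matrix(1), h12 = matrix(2), h22 = matrix(3),
                      sigma = 1), class = "hessian_field")
  expect_equal(rotate_hessian(h, 0), h)
  hq <- rotate_hessian(h, pi / 2)
  expect_equal(c(hq$h11, hq$h12, hq$h22), c(3, -2, 1))
  e <- eigen_decompose(rotate_hessian(
    structure(list(h11 = matrix(2), h12 = matrix(1), h22 = matrix(2), sigma = 1),
              class = "hessian_field"), 0.7))
  expect_equal(c(e$lambda1, e$lambda2), c(1, 3))
})

test_that("vesselness difference equals the discriminant and scores ridges", {
  set.seed(24)
  n <- 200
  h <- structure(list(h11 = matrix(rnorm(n), n, 1), h12 = matrix(rnorm(n), n, 1),
                      h22 = matrix(rnorm(n), n, 1), sigma = 1),
                 class = "hessian_field")
  v <- vesselness_difference(eigen_decompose(h), rescale = FALSE)
  expect_true(all(v >= 0))
  expect_equal(v, sqrt((h$h11 - h$h22)^2 + 4 * h$h12^2), tolerance = 1e-12)

  iso <- structure(list(h11 = matrix(2), h12 = matrix(1), h22 = matrix(2),
                        sigma = 1), class = "hessian_field")
  expect_equal(as.vector(vesselness_difference(eigen_decompose(iso),
                                               rescale = FALSE)), 2)

  # synthetic bright Gaussian ridge: centerline response dominates background
  xs <- matrix(rep(1:64, each = 64), 64, 64)
  ridge <- 0.4 * exp(-(xs - 32)^2 / (2 * (3 / 2.355)^2))
  v <- enhance_at_scale(ridge, 1.5, rescale = FALSE)
  expect_gt(median(v[, 32]), 5 * median(v[, c(1:10, 55:64)]))
})

test_that("scale-normalized response is maximized near the ridge width", {
  xs <- matrix(rep(1:96, each = 96), 96, 96)
  w <- 3
  ridge <- 0.4 * exp(-(xs - 48)^2 / (2 * (w / 2.355)^2))
  resp <- vapply(c(0.5, 1, 1.5, 2, 2.5, 3), function(s)
    mean(enhance_at_scale(ridge, s, rescale = FALSE)[, 48]), numeric(1))
  expect_true(which.max(resp) %in% 2:4)  # peak near sigma ~ w
})
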