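test_that("histograms quantize and restrict to the FOV as specified", {
  img <- matrix(c(0.1, 0.1, 0.1, 0.9, 0.9, 0.9), 2, 3)
  fov <- matrix(1L, 2, 3)
  h <- build_histogram(img, fov, L = 10)
  expect_equal(h$counts[2], 3)   # floor(0.1*9+0.5) = 1
  expect_equal(h$counts[9], 3)   # floor(0.9*9+0.5) = 8
  expect_equal(sum(h$counts), 6)
  expect_equal(sum(h$p), 1)

  z <- build_histogram(matrix(0, 4, 4), matrix(1L, 4, 4), L = 256)
  expect_equal(z$counts[1], 16)
  expect_equal(sum(z$counts[-1]), 0)

  half <- build_histogram(matrix(rep(c(0, 1), 8), 4, 4), matrix(1L, 4, 4), 256)
  expect_equal(half$p[c(1, 256)], c(0.5, 0.5))

  fov2 <- matrix(0L, 2, 3); fov2[1, 1] <- 1L
  expect_equal(build_histogram(img, fov2, 10)$n, 1)
  expect_error(build_histogram(img, matrix(0L, 2, 3), 10),
               class = "vseg_empty_fov")
})

test_that("Otsu picks the documented split on constructed histograms", {
  h <- build_histogram(matrix(c(0.1, 0.1, 0.1, 0.9, 0.9, 0.9), 2, 3),
                       matrix(1L, 2, 3), L = 10)
  ot <- otsu_threshold(h)
  # all t in 1..7 give identical between-class variance; smallest wins
  expect_equal(ot$t_star, 1L)
  bf <- bf_otsu(h$counts)
  expect_equal(ot$t_star, bf$t_star)

  spikes <- structure(list(counts = c(5L, rep(0L, 254), 5L),
                           p = c(0.5, rep(0, 254), 0.5), L = 256L, n = 10L),
                      class = "gray_histogram")
  ot <- otsu_threshold(spikes)
  expect_equal(ot$t_star, 0L)
  expect_equal(ot$stats$omega0, 0.5)
  expect_equal(ot$stats$omega1, 0.5)
  expect_equal(ot$stats$sigma2_W, 0)

  degen <- structure(list(counts = c(0L, 7L, rep(0L, 6)),
                          p = c(0, 1, rep(0, 6)), L = 8L, n = 7L),
                     class = "gray_histogram")
  expect_error(otsu_threshold(degen), class = "vseg_degenerate_histogram")
})

test_that("Otsu agrees with brute force and the variance decomposition holds", {
  set.seed(31)
  n_hist <- 400
  for (i in seq_len(n_hist)) {
    L <- sample(2:32, 1)
    counts <- rpois(L, lambda = sample(c(1, 5, 50), 1))
    if (sum(counts > 0) < 2) counts[c(1, L)] <- counts[c(1, L)] + 1L
    hist <- structure(list(counts = counts, p = counts / sum(counts),
                           L = L, n = sum(counts)), class = "gray_histogram")
    ot <- otsu_threshold(hist)
    bf <- bf_otsu(counts)
    # identical split, or an exact tie resolved differently by float noise
    expect_true(ot$t_star == bf$t_star ||
                  abs(bf$s2b[ot$t_star + 1L] - bf$s2b[bf$t_star + 1L]) <=
                    1e-12 * max(bf$s2b[bf$t_star + 1L], 1e-12))
    expect_rel_equal(ot$stats$sigma2_B, bf$s2b[ot$t_star + 1L], 1e-9)
    # decomposition at the optimum, against independently coded variances
    cv <- bf_class_variances(counts, ot$t_star)
    expect_rel_equal(ot$stats$sigma2_B + cv$s2w, cv$s2t, 1e-9)
    expect_rel_equal(ot$stats$sigma2_W, cv$s2w, 1e-9, scale_floor = 1e-6)
    expect_true(ot$stats$beta >= 0 && ot$stats$beta <= 1)
  }
})

test_that("thresholding is inclusive and FOV-restricted", {
  img <- matrix(c(0.2, 0.5, 0.8), 1, 3)
  expect_equal(as.vector(apply_threshold(img, 0.5)), c(0L, 1L, 1L))
  expect_equal(apply_threshold(img, 0), matrix(1L, 1, 3))
  expect_equal(apply_threshold(img, 0.81), matrix(0L, 1, 3))
  fov <- matrix(c(1L, 0L, 1L), 1, 3)
  expect_equal(as.vector(apply_threshold(img, 0, fov)), c(1L, 0L, 1L))
})

test_that("fusion saturates wide-vessel pixels and nothing else", {
  thin <- matrix(0.3, 8, 8)
  empty <- matrix(0L, 8, 8)
  expect_equal(fuse_wide_into_thin(thin, empty), thin)
  ones <- matrix(1L, 8, 8)
  expect_equal(fuse_wide_into_thin(thin, ones), matrix(1, 8, 8))
  blob <- matrix(0L, 8, 8); blob[3:5, 3:5] <- 1L
  fused <- fuse_wide_into_thin(thin, blob)
  expect_equal(fused[blob == 1L], rep(1, 9))
  expect_equal(fused[blob == 0L], rep(0.3, 55))
  expect_error(fuse_wide_into_thin(thin, matrix(0L, 4, 4)),
               class = "vseg_shape_mismatch")
})

test_that("region threshold map raises near wide vessels and lowers away", {
  wm <- matrix(0L, 9, 9); wm[5, 5] <- 1L
  tm <- region_threshold_map(0.5, wm, offset = 0.05, radius = 2)
  expect_equal(sum(tm$values == 0.55), 13)   # disk radius 2 footprint
  expect_equal(sum(tm$values == 0.45), 81 - 13)

  tm0 <- region_threshold_map(0.5, wm, offset = 0, radius = 2)
  expect_equal(unique(as.vector(tm0$values)), 0.5)
  tme <- region_threshold_map(0.5, matrix(0L, 9, 9), offset = 0.05, radius = 2)
  expect_equal(unique(as.vector(tme$values)), 0.45)
  # clamping at the range ends
  tmc <- region_threshold_map(0.98, wm, offset = 0.05, radius = 1)
  expect_equal(max(tmc$values), 1)
})

test_that("classification keeps wide vessels and hand-built thin lines", {
  fused <- matrix(0, 8, 8)
  wm <- matrix(0L, 8, 8)
  tm <- region_threshold_map(0.5, wm, 0.05, 2)
  expect_equal(classify_pixels(fused, tm, wm), matrix(0L, 8, 8))

  # one wide blob, one faint line at 0.48: kept only outside the blob's
  # neighborhood where the threshold is 0.5 - 0.05 = 0.45
  wm[2:3, 2:3] <- 1L
  fused <- matrix(0, 8, 8)
  fused[wm == 1L] <- 1
  fused[, 7] <- 0.48
  tm <- region_threshold_map(0.5, wm, 0.05, 2)
  got <- classify_pixels(fused, tm, wm)
  expect_true(all(got[wm == 1L] == 1L))          # superset of wide mask
  expect_equal(got[1:8, 7], rep(1L, 8))          # line beyond the radius
  expect_equal(sum(got), sum(wm) + 8)

  # monotonicity: larger offset never adds pixels inside the neighborhood
  # and never removes pixels outside it
  set.seed(32)
  img <- matrix(runif(144), 12, 12)
  wm2 <- matrix(0L, 12, 12); wm2[6, 6] <- 1L
  nb <- region_threshold_map(0.5, wm2, 0, 3)$values  # uniform ref
  lo <- classify_pixels(img, region_threshold_map(0.5, wm2, 0.02, 3), wm2)
  hi <- classify_pixels(img, region_threshold_map(0.5, wm2, 0.10, 3), wm2)
  inside <- (vesselseg:::morph_apply(wm2 + 0, disk_se(3), "dilate") > 0.5)
  expect_true(all(hi[inside] <= lo[inside]))
  expect_true(all(hi[!inside] >= lo[!inside]))
})
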