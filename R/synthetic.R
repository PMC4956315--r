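# Synthetic fundus phantom: random vessel trees with Gaussian cross-section
# profiles, dark-on-bright polarity, a radial illumination gradient, additive
# Gaussian noise and a circular field-of-view aperture -- the image features
# the segmentation pipeline assumes, with exact ground truth.

#' Specification of a synthetic fundus sample
#'
#' @param frame image height and width in pixels.
#' @param fov_radius radius of the circular aperture.
#' @param n_trees number of vessel trees rooted on the FOV boundary.
#' @param width_range vessel widths in pixels, within \[1, 8\]; presets:
#'   `"thin"` = c(1, 2), `"wide"` = c(6, 8), `"default"` = c(1, 8).
#' @param vessel_contrast intensity depth of vessels below the background.
#' @param background_level background intensity at the FOV center.
#' @param illumination_gradient intensity drop from FOV center to edge.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param branching_prob per-step probability that a branch spawns a child.
#' @param seed integer seed; every draw of the generator flows from it.
#' @param preset convenience override of `width_range`.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(frame = c(256, 256), fov_radius = 118,
                           n_trees = 4, width_range = c(1, 8),
                           vessel_contrast = 0.25, background_level = 0.65,
                           illumination_gradient = 0.1, noise_sd = 0.02,
                           branching_prob = 0.006, seed = 1,
                           preset = c("default", "thin", "wide")) {
  preset <- match.arg(preset)
  if (preset == "thin") width_range <- c(1, 2)
  if (preset == "wide") width_range <- c(6, 8)
  if (width_range[1] < 1 || width_range[2] > 8 || diff(width_range) < 0)
    vseg_error("width_range must be increasing and within [1, 8]",
               "vseg_bad_input")
  if (vessel_contrast < 0 || background_level - vessel_contrast < 0 ||
      background_level > 1)
    vseg_error("intensities must stay clampable to [0,1]", "vseg_bad_input")
  structure(list(frame = as.integer(frame), fov_radius = fov_radius,
                 n_trees = as.integer(n_trees), width_range = width_range,
                 vessel_contrast = vessel_contrast,
                 background_level = background_level,
                 illumination_gradient = illumination_gradient,
                 noise_sd = noise_sd, branching_prob = branching_prob,
                 seed = as.integer(seed), preset = preset),
            class = "synthetic_spec")
}

# Run fn under a fixed, named RNG state; the caller's state is untouched.
with_generator_rng <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  fn()
}

#' Generate the centerlines of one random vessel tree
#'
#' Recursive random-walk tree: the root sits on the FOV boundary heading
#' inward; centerlines advance in unit steps with bounded curvature; width
#' tapers monotonically along a branch and drops from parent to child, all
#' widths clamped to `width_range`; branches terminate at the FOV edge.
#' Must be called inside the generator's seeded RNG context ([render_synthetic()]
#' does this); calling it directly uses the session RNG.
#'
#' @param spec a `synthetic_spec`.
#' @param root_angle angle (radians) of the root on the FOV boundary;
#'   drawn uniformly when `NULL`. [render_synthetic()] roots all trees of a
#'   sample near one angle, mimicking vessels radiating from the optic disc.
#' @param heading_offset angle added to the inward initial heading; the
#'   renderer fans the trees of a sample across distinct offsets so they
#'   spread instead of criss-crossing.
#' @return data frame with columns `y`, `x` (pixel coordinates, 1-based,
#'   row/col) and `width` (pixels), one row per centerline point.
#' @export
generate_vessel_tree <- function(spec, root_angle = NULL, heading_offset = 0) {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$frame[1]; w <- spec$frame[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  wmin <- spec$width_range[1]; wmax <- spec$width_range[2]
  phi <- if (is.null(root_angle)) stats::runif(1, 0, 2 * pi) else root_angle
  root_r <- min(0.97 * spec$fov_radius, spec$fov_radius - 3)
  root <- c(cy + root_r * sin(phi), cx + root_r * cos(phi))
  # branch queue: y, x, direction, width, depth
  queue <- list(list(y = root[1], x = root[2],
                     dir = phi + pi + heading_offset + stats::runif(1, -0.15, 0.15),
                     width = stats::runif(1, 0.55 * wmax, wmax), depth = 0))
  pts <- vector("list", 64); np <- 0
  max_depth <- 3
  while (length(queue) > 0) {
    b <- queue[[1]]; queue <- queue[-1]
    y <- b$y; x <- b$x; dir <- b$dir; wd <- max(wmin, min(wmax, b$width))
    heading <- dir   # branches curve gently about their initial heading
    for (step in seq_len(320)) {
      r <- sqrt((y - cy)^2 + (x - cx)^2)
      if (r > spec$fov_radius - 2) break
      np <- np + 1
      if (np > length(pts)) pts <- c(pts, vector("list", length(pts)))
      pts[[np]] <- c(y, x, wd)
      jit <- max(-0.15, min(0.15, stats::rnorm(1, 0, 0.05)))
      dir <- dir + jit + 0.04 * sin(heading - dir)
      y <- y + sin(dir); x <- x + cos(dir)
      wd <- max(wmin, wd * 0.996)
      if (b$depth < max_depth && stats::runif(1) < spec$branching_prob) {
        side <- sample(c(-1, 1), 1)
        queue[[length(queue) + 1]] <- list(
          y = y, x = x, dir = dir + side * stats::runif(1, 0.35, 0.8),
          width = max(wmin, wd * 0.7), depth = b$depth + 1)
        wd <- max(wmin, wd * 0.9)
      }
    }
  }
  if (np == 0) return(data.frame(y = numeric(0), x = numeric(0), width = numeric(0)))
  m <- do.call(rbind, pts[seq_len(np)])
  data.frame(y = m[, 1], x = m[, 2], width = pmin(pmax(m[, 3], wmin), wmax))
}

#' Render a synthetic fundus sample
#'
#' Builds the full phantom: `n_trees` vessel trees rendered as dark
#' Gaussian cross-section profiles (depth `vessel_contrast`, full width at
#' half maximum equal to the local vessel width) subtracted from a radially
#' decaying background, plus i.i.d. Gaussian noise, clamped to \[0,1\] and
#' windowed by the circular aperture. The truth mask marks pixels within
#' half a width of any centerline; red and blue planes carry the same scene
#' at lower vessel contrast, mimicking real fundus channel statistics.
#'
#' Fully deterministic given `spec$seed`.
#'
#' @param spec a `synthetic_spec`.
#' @return object of class `synthetic_sample`: `image` (h x w x 3 array),
#'   `truth` and `fov` (0/1 matrices), and the `spec`.
#' @export
render_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_generator_rng(spec$seed, function() {
    h <- spec$frame[1]; w <- spec$frame[2]
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    rr <- outer((1:h - cy)^2, (1:w - cx)^2, "+")
    fov <- (rr <= spec$fov_radius^2) * 1L

    depth <- matrix(0, h, w)   # vessel profile, max over centerline points
    truth <- matrix(0L, h, w)
    # All trees root near one boundary location (the optic disc) and fan
    # inward at distinct headings, as retinal arcades do.
    disc_angle <- stats::runif(1, 0, 2 * pi)
    fan <- if (spec$n_trees > 1) {
      seq(-0.85, 0.85, length.out = spec$n_trees)
    } else 0
    for (k in seq_len(spec$n_trees)) {
      tree <- generate_vessel_tree(spec,
                                   root_angle = disc_angle + stats::runif(1, -0.12, 0.12),
                                   heading_offset = fan[k])
      for (i in seq_len(nrow(tree))) {
        py <- tree$y[i]; px <- tree$x[i]; wd <- tree$width[i]
        # sd = width/3.2: the visibly dark extent (dip above twice the
        # noise floor) is close to the stated width, while a unit-width
        # vessel still dips ~3 noise sd at its nearest pixel.
        s <- wd / 3.2
        half <- wd / 2
        ext <- ceiling(2.5 * s + 1)
        r0 <- max(1, floor(py - ext)); r1 <- min(h, ceiling(py + ext))
        c0 <- max(1, floor(px - ext)); c1 <- min(w, ceiling(px + ext))
        if (r0 > r1 || c0 > c1) next
        d2 <- outer((r0:r1 - py)^2, (c0:c1 - px)^2, "+")
        depth[r0:r1, c0:c1] <- pmax(depth[r0:r1, c0:c1], exp(-d2 / (2 * s^2)))
        truth[r0:r1, c0:c1] <- pmax(truth[r0:r1, c0:c1], (d2 <= half^2) * 1L)
      }
    }
    truth <- truth * fov

    radial <- sqrt(rr) / spec$fov_radius
    bg <- spec$background_level - spec$illumination_gradient * radial^2
    green <- bg - spec$vessel_contrast * depth +
      stats::rnorm(h * w, 0, spec$noise_sd)
    red <- clamp01(bg * 1.25) - 0.4 * spec$vessel_contrast * depth +
      stats::rnorm(h * w, 0, spec$noise_sd)
    blue <- bg * 0.45 - 0.15 * spec$vessel_contrast * depth +
      stats::rnorm(h * w, 0, spec$noise_sd)
    img <- array(0, c(h, w, 3))
    dark <- 0.02
    img[, , 1] <- clamp01(ifelse(fov == 1L, red, dark))
    img[, , 2] <- clamp01(ifelse(fov == 1L, green, dark))
    img[, , 3] <- clamp01(ifelse(fov == 1L, blue, dark))
    structure(list(image = img, truth = truth, fov = fov, spec = spec),
              class = "synthetic_sample")
  })
}
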