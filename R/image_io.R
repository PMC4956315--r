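#' Read a raster image as normalized intensities
#'
#' Loads PNG, TIFF, JPEG, or PNM (PPM/PGM) rasters and normalizes every
#' sample to \[0,1\] by the format's maximum sample value. Single-channel
#' files return a gray matrix (rows = image rows); color files return an
#' h x w x 3 array with red, green, blue planes.
#'
#' GIF is not readable in this build and raises the same named error as any
#' other unsupported format.
#'
#' @param path path to the image file.
#' @return a numeric matrix (gray) or h x w x 3 numeric array (color),
#'   intensities in \[0,1\].
#' @seealso [write_binary()], [extract_green()]
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    vseg_error(sprintf("file not found: %s", path), "vseg_file_not_found")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png", "tif", "tiff", "jpg", "jpeg")) {
    img <- tryCatch(EBImage::readImage(path),
                    error = function(e) vseg_error(
                      sprintf("unreadable image %s: %s", path, conditionMessage(e)),
                      "vseg_unreadable_file"))
    dat <- EBImage::imageData(img)
    # EBImage stores (x, y[, c]); internal convention is (row, col[, c]).
    if (length(dim(dat)) == 2L) return(clamp01(t(dat)))
    if (dim(dat)[3] >= 3L) {
      out <- aperm(dat[, , 1:3, drop = FALSE], c(2L, 1L, 3L))
      return(clamp01(out))
    }
    return(clamp01(t(dat[, , 1L])))
  }
  if (ext %in% c("ppm", "pgm", "pnm")) return(read_pnm(path))
  vseg_error(sprintf("unsupported image format '.%s' (%s)", ext, path),
             "vseg_unsupported_format")
}

# Minimal PNM reader: P2/P5 (gray) and P3/P6 (color), ASCII or binary,
# maxval up to 65535. Returns the same containers as read_image().
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  token <- local({
    buf <- character(0)
    function() {
      while (length(buf) == 0) {
        line <- readLines(con, n = 1, warn = FALSE)
        if (length(line) == 0)
          vseg_error(sprintf("truncated PNM header in %s", path),
                     "vseg_unreadable_file")
        line <- sub("#.*$", "", line)
        buf <<- strsplit(trimws(line), "[[:space:]]+")[[1]]
        buf <<- buf[nzchar(buf)]
      }
      t <- buf[1]; buf <<- buf[-1]; t
    }
  })
  magic <- token()
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    vseg_error(sprintf("unsupported PNM magic '%s' in %s", magic, path),
               "vseg_unsupported_format")
  w <- as.integer(token()); h <- as.integer(token())
  maxval <- as.integer(token())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  nvals <- w * h * nch
  vals <- if (magic %in% c("P2", "P3")) {
    scan(con, what = integer(), n = nvals, quiet = TRUE, comment.char = "#")
  } else if (maxval < 256L) {
    as.integer(readBin(con, "raw", n = nvals))
  } else {
    readBin(con, "integer", n = nvals, size = 2, signed = FALSE, endian = "big")
  }
  if (length(vals) != nvals)
    vseg_error(sprintf("truncated PNM data in %s", path), "vseg_unreadable_file")
  x <- vals / maxval
  if (nch == 1L) {
    matrix(x, nrow = h, ncol = w, byrow = TRUE)
  } else {
    arr <- array(0, c(h, w, 3L))
    for (k in 1:3)
      arr[, , k] <- matrix(x[seq(k, nvals, by = 3L)], h, w, byrow = TRUE)
    arr
  }
}

#' Extract the green channel of a color image
#'
#' In fundus photographs the green band shows the strongest vessel-to-
#' background contrast (red is near-saturated, blue is dark and noisy), so
#' the whole pipeline operates on it.
#'
#' @param img an h x w x 3 color array as returned by [read_image()].
#' @return the green plane as a gray matrix.
#' @export
extract_green <- function(img) {
  if (!is_color_image(img))
    vseg_error("input has no green channel: a 3-channel color image is required",
               "vseg_missing_channel")
  img[, , 2L]
}

#' Estimate the circular field-of-view mask of a fundus photograph
#'
#' Fundus cameras image through a circular aperture; pixels outside it are
#' nearly black. The mask is estimated as channel-mean luminance above a
#' threshold, morphologically closed (disk radius 5) to heal rim pixels,
#' keeping only the largest connected component. Prefer a camera-supplied
#' mask when one exists (DRIVE ships them); this estimate is the fallback.
#'
#' @param img gray matrix or color array.
#' @param luminance_threshold luminance cut in (0,1); default 0.05.
#' @return integer 0/1 matrix; all zeros when nothing exceeds the threshold.
#' @export
estimate_fov_mask <- function(img, luminance_threshold = 0.05) {
  if (luminance_threshold <= 0 || luminance_threshold >= 1)
    vseg_error("luminance_threshold must lie in (0,1)", "vseg_bad_input")
  lum <- if (is_color_image(img)) (img[, , 1] + img[, , 2] + img[, , 3]) / 3 else img
  assert_gray(lum)
  raw <- (lum > luminance_threshold) * 1L
  if (!any(raw == 1L)) return(matrix(0L, nrow(lum), ncol(lum)))
  closed <- (morph_close(raw + 0, disk_se(5)) > 0.5) * 1L
  cc <- label_components(closed, connectivity = 8)
  keep <- which.max(cc$sizes)
  out <- (cc$labels == keep) * 1L
  out
}

#' Write a gray or color image as an 8-bit PNG
#'
#' @param img gray matrix or h x w x 3 array, intensities in \[0,1\].
#' @param path output path; the parent directory must exist.
#' @export
write_image_png <- function(img, path) {
  if (!dir.exists(dirname(path)))
    vseg_error(sprintf("cannot write %s: directory does not exist", path),
               "vseg_unwritable_path")
  obj <- if (is_color_image(img)) {
    EBImage::Image(aperm(clamp01(img), c(2L, 1L, 3L)), colormode = "Color")
  } else {
    assert_gray(img)
    t(clamp01(img))
  }
  EBImage::writeImage(obj, path, type = "png", bits.per.sample = 8L)
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground is written as 255, background as 0, so that reading the file
#' back with [read_image()] and thresholding at 0.5 reproduces the mask
#' exactly.
#'
#' @param mask integer 0/1 matrix.
#' @param path output path; the parent directory must exist.
#' @export
write_binary <- function(mask, path) {
  assert_mask(mask)
  if (!dir.exists(dirname(path)))
    vseg_error(sprintf("cannot write %s: directory does not exist", path),
               "vseg_unwritable_path")
  EBImage::writeImage(t(mask + 0), path, type = "png", bits.per.sample = 8L)
  invisible(path)
}
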