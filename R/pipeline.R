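# Orchestration of the full segmentation flow:
# green -> CLAHE -> complement -> modified top-hat -> two-scale Hessian
# vesselness -> global Otsu on the wide image -> fusion -> region-based
# offset thresholding -> area filtering.

#' Pipeline configuration
#'
#' All tunable parameters of the segmentation pipeline with their defaults.
#' Serializable to/from a flat JSON document via [write_config()] /
#' [read_config()].
#'
#' @param clahe_clip CLAHE clip limit, fraction of tile area in \[0, 0.01\].
#' @param clahe_tiles CLAHE tile grid `c(rows, cols)`.
#' @param tophat_radius disk radius of the top-hat structuring elements.
#' @param sigma_thin,sigma_wide Hessian scales for thin and wide vessels.
#' @param histogram_levels gray levels for the Otsu histogram.
#' @param region_offset threshold offset of the region-based map.
#' @param neighborhood_radius dilation radius defining "near wide vessels".
#' @param min_component_keep smallest component area, in pixels, kept by
#'   the final area filter (components of `min_component_keep - 1` pixels
#'   or fewer are removed).
#' @param connectivity component connectivity, 4 or 8.
#' @param eval_region `"fov"` or `"full"`: region metrics are computed on.
#' @param save_intermediates keep the per-stage image trace.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(clahe_clip = 0.01, clahe_tiles = c(8, 8),
                            tophat_radius = 8, sigma_thin = 1,
                            sigma_wide = 2.5, histogram_levels = 256,
                            region_offset = 0.05, neighborhood_radius = 8,
                            min_component_keep = 31, connectivity = 8,
                            eval_region = c("fov", "full"),
                            save_intermediates = FALSE) {
  eval_region <- match.arg(eval_region)
  if (sigma_thin <= 0 || sigma_wide <= sigma_thin)
    vseg_error("scales must satisfy 0 < sigma_thin < sigma_wide",
               "vseg_bad_input")
  if (min_component_keep < 1)
    vseg_error("min_component_keep must be >= 1", "vseg_bad_input")
  structure(list(clahe_clip = clahe_clip, clahe_tiles = as.integer(clahe_tiles),
                 tophat_radius = as.integer(tophat_radius),
                 sigma_thin = sigma_thin, sigma_wide = sigma_wide,
                 histogram_levels = as.integer(histogram_levels),
                 region_offset = region_offset,
                 neighborhood_radius = as.integer(neighborhood_radius),
                 min_component_keep = as.integer(min_component_keep),
                 connectivity = as.integer(connectivity),
                 eval_region = eval_region,
                 save_intermediates = isTRUE(save_intermediates)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

#' Segment the blood vessels of a fundus image
#'
#' Runs the full unsupervised pipeline. Stages, in order: green-channel
#' extraction, CLAHE, min-max normalization over the FOV, complementation
#' (vessels become bright), modified top-hat background removal, Hessian
#' eigenvalue-difference enhancement at the wide and thin scales, global
#' Otsu threshold on the wide image, fusion of the wide binary map into the
#' thin image, region-based offset thresholding, and removal of small
#' components. Pixels outside the FOV are replaced by the mean inside-FOV
#' intensity before enhancement so the aperture rim does not masquerade as
#' a vessel.
#'
#' @param img color array (h x w x 3) or gray matrix (already the green
#'   channel).
#' @param fov optional 0/1 FOV matrix; estimated with [estimate_fov_mask()]
#'   when missing.
#' @param cfg a [pipeline_config()].
#' @return object of class `vessel_segmentation`: `mask` (final 0/1
#'   matrix), `fov`, `t_global` (the global Otsu threshold used), `otsu`
#'   (its `otsu_stats`), and `trace` (named per-stage images when
#'   `cfg$save_intermediates`, else `NULL`; stages `green`, `clahe`,
#'   `tophat`, `thin_enhanced`, `wide_enhanced`, `wide_binary`, `fused`,
#'   `local_binary`, `final`).
#' @export
segment_vessels <- function(img, fov = NULL, cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  green <- if (is_color_image(img)) extract_green(img) else img
  assert_gray(green, "green channel")
  if (is.null(fov)) fov <- estimate_fov_mask(img)
  assert_mask(fov, "fov")
  assert_same_shape(green, fov, "green/fov")
  if (!any(fov == 1L))
    vseg_error("empty FOV: nothing to segment", "vseg_empty_fov")

  run <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      vseg_error(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
                 "vseg_stage_error")
    })
  }
  inside <- fov == 1L
  green_f <- green
  green_f[!inside] <- mean(green[inside])

  cl <- run("clahe", clahe(green_f, cfg$clahe_clip, cfg$clahe_tiles))
  cl <- minmax_rescale(cl, fov)
  cl[!inside] <- mean(cl[inside])
  inv <- complement_image(cl)
  th <- run("tophat", modified_top_hat(inv, disk_se(cfg$tophat_radius),
                                       disk_se(cfg$tophat_radius)))
  wide_enh <- run("hessian_wide", enhance_at_scale(th, cfg$sigma_wide, fov))
  thin_enh <- run("hessian_thin", enhance_at_scale(th, cfg$sigma_thin, fov))

  hist <- run("otsu", build_histogram(wide_enh, fov, cfg$histogram_levels))
  ot <- tryCatch(otsu_threshold(hist),
                 vseg_degenerate_histogram = function(e) NULL)
  if (is.null(ot)) {
    # constant vesselness field: nothing tubular anywhere -> empty mask
    empty <- matrix(0L, nrow(green), ncol(green))
    trace <- NULL
    if (cfg$save_intermediates)
      trace <- list(green = green, clahe = cl, tophat = th,
                    thin_enhanced = thin_enh, wide_enhanced = wide_enh,
                    wide_binary = empty, fused = thin_enh,
                    local_binary = empty, final = empty)
    return(structure(list(mask = empty, fov = fov, t_global = NA_real_,
                          otsu = NULL, trace = trace),
                     class = "vessel_segmentation"))
  }
  t_global <- ot$threshold
  wide_mask <- apply_threshold(wide_enh, t_global, fov)
  fused <- fuse_wide_into_thin(thin_enh, wide_mask)
  tmap <- region_threshold_map(t_global, wide_mask, cfg$region_offset,
                               cfg$neighborhood_radius)
  local_bin <- classify_pixels(fused, tmap, wide_mask) * fov
  final <- run("postprocess",
               area_filter(local_bin, cfg$min_component_keep - 1L,
                           cfg$connectivity))

  trace <- NULL
  if (cfg$save_intermediates)
    trace <- list(green = green, clahe = cl, tophat = th,
                  thin_enhanced = thin_enh, wide_enhanced = wide_enh,
                  wide_binary = wide_mask, fused = fused,
                  local_binary = local_bin, final = final)
  structure(list(mask = final, fov = fov, t_global = t_global,
                 otsu = ot$stats, trace = trace),
            class = "vessel_segmentation")
}

#' Batch-segment a folder of fundus images
#'
#' Segments every readable raster in `image_dir`, writes the binary masks
#' to `out_dir`, and -- when a truth directory is given -- evaluates each
#' mask against the ground-truth file sharing its stem and writes per-image
#' plus average metrics as `metrics.csv` / `metrics.json`.
#'
#' @param image_dir directory of input images.
#' @param truth_dir optional directory of manual segmentation masks.
#' @param fov_dir optional directory of FOV masks; estimated when absent.
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param verbose log stage progress.
#' @return invisibly, the metrics data frame (or `NULL` without truths).
#' @export
run_dataset <- function(image_dir, truth_dir = NULL, fov_dir = NULL,
                        cfg = pipeline_config(), out_dir, verbose = TRUE) {
  if (!dir.exists(image_dir))
    vseg_error(sprintf("image_dir does not exist: %s", image_dir),
               "vseg_file_not_found")
  exts <- "\\.(png|tif|tiff|jpg|jpeg|ppm|pgm|pnm)$"
  files <- sort(list.files(image_dir, pattern = exts, ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0)
    vseg_error(sprintf("no readable images in %s", image_dir),
               "vseg_empty_input")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  find_mate <- function(dir, stem) {
    if (is.null(dir)) return(NULL)
    hits <- list.files(dir, pattern = paste0("^", stem, exts),
                       ignore.case = TRUE, full.names = TRUE)
    if (length(hits) == 0) NULL else hits[[1]]
  }
  records <- list()
  for (f in files) {
    stem <- tools::file_path_sans_ext(basename(f))
    if (verbose) message(sprintf("[vesselseg] segmenting %s", basename(f)))
    img <- read_image(f)
    fov_file <- find_mate(fov_dir, stem)
    fov <- if (!is.null(fov_file)) (read_image(fov_file) >= 0.5) * 1L else NULL
    t0 <- Sys.time()
    seg <- segment_vessels(img, fov = fov, cfg = cfg)
    if (verbose) message(sprintf("[vesselseg]   done in %.1fs",
                                 as.numeric(Sys.time() - t0, units = "secs")))
    write_binary(seg$mask, file.path(out_dir, paste0(stem, "_mask.png")))
    if (!is.null(truth_dir)) {
      tf <- find_mate(truth_dir, stem)
      if (is.null(tf)) {
        warning(sprintf("no ground truth for %s: skipped in metrics", stem))
        next
      }
      truth <- (read_image(tf) >= 0.5) * 1L
      if (length(dim(truth)) == 3L) truth <- truth[, , 1]
      ev_fov <- if (cfg$eval_region == "fov") seg$fov else NULL
      records[[stem]] <- compute_metrics(
        confusion_counts(seg$mask, truth, ev_fov), image_id = stem)
    }
  }
  if (length(records) == 0) return(invisible(NULL))
  df <- write_metrics(records, file.path(out_dir, "metrics"))
  invisible(df)
}
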