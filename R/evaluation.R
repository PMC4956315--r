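# Pixel-wise segmentation metrics: accuracy, sensitivity, specificity and
# their summary AUC = (Sn + Sp) / 2, per image and averaged over a dataset.

#' Confusion counts between a predicted and a reference mask
#'
#' Tallies TP/TN/FP/FN over the field of view when a FOV mask is given,
#' otherwise over the full frame. Vessel = 1, background = 0.
#'
#' @param pred predicted 0/1 matrix.
#' @param truth reference (manually segmented) 0/1 matrix.
#' @param fov optional 0/1 matrix restricting the evaluated region.
#' @return object of class `confusion_counts`: integers `TP`, `TN`, `FP`,
#'   `FN` and the evaluated region (`"fov"` or `"full"`).
#' @export
confusion_counts <- function(pred, truth, fov = NULL) {
  assert_mask(pred, "pred")
  assert_mask(truth, "truth")
  assert_same_shape(pred, truth, "pred/truth")
  if (!is.null(fov)) {
    assert_mask(fov, "fov")
    assert_same_shape(pred, fov, "pred/fov")
    if (!any(fov == 1L))
      vseg_error("empty FOV: nothing to evaluate", "vseg_empty_fov")
    sel <- fov == 1L
    p <- pred[sel]; g <- truth[sel]
    region <- "fov"
  } else {
    p <- as.vector(pred); g <- as.vector(truth)
    region <- "full"
  }
  structure(list(
    TP = sum(p == 1L & g == 1L),
    TN = sum(p == 0L & g == 0L),
    FP = sum(p == 1L & g == 0L),
    FN = sum(p == 0L & g == 1L),
    region = region
  ), class = "confusion_counts")
}

#' Build a metrics record from accuracy, sensitivity and specificity
#'
#' The summary AUC is always recomputed as (sn + sp) / 2.
#'
#' @param acc,sn,sp metric values in \[0,1\] (`acc` may be `NA` when only
#'   sn/sp are known).
#' @param image_id identifier carried through reports.
#' @param region evaluated region label.
#' @return object of class `metrics_record` with fields `acc`, `sn`, `sp`,
#'   `auc`, `image_id`, `region`.
#' @export
metrics_record <- function(acc = NA_real_, sn, sp, image_id = NA_character_,
                           region = NA_character_) {
  structure(list(acc = acc, sn = sn, sp = sp, auc = (sn + sp) / 2,
                 image_id = image_id, region = region),
            class = "metrics_record")
}

#' Segmentation metrics from confusion counts
#'
#' Acc = (TP+TN)/(TP+FP+TN+FN), Sn = TP/(TP+FN), Sp = TN/(TN+FP),
#' AUC = (Sn+Sp)/2. Sensitivity is undefined when the reference contains no
#' vessel pixels and specificity when it contains no background pixels;
#' both raise named errors rather than returning NaN.
#'
#' @param counts a `confusion_counts` object.
#' @param image_id identifier carried into the record.
#' @return a `metrics_record`.
#' @export
compute_metrics <- function(counts, image_id = NA_character_) {
  stopifnot(inherits(counts, "confusion_counts"))
  tot <- counts$TP + counts$TN + counts$FP + counts$FN
  if (tot == 0) vseg_error("no evaluated pixels", "vseg_empty_fov")
  if (counts$TP + counts$FN == 0)
    vseg_error("sensitivity undefined: reference has no vessel pixels",
               "vseg_undefined_sensitivity")
  if (counts$TN + counts$FP == 0)
    vseg_error("specificity undefined: reference has no background pixels",
               "vseg_undefined_specificity")
  metrics_record(acc = (counts$TP + counts$TN) / tot,
                 sn = counts$TP / (counts$TP + counts$FN),
                 sp = counts$TN / (counts$TN + counts$FP),
                 image_id = image_id, region = counts$region)
}

#' Average metrics over a dataset
#'
#' Unweighted arithmetic mean of per-image accuracy, sensitivity and
#' specificity (the convention of published DRIVE/STARE result tables);
#' the summary AUC is recomputed from the mean sensitivity and mean
#' specificity.
#'
#' @param records list of `metrics_record` objects.
#' @return a `metrics_record` with `image_id = "average"`.
#' @export
aggregate_metrics <- function(records) {
  if (length(records) == 0)
    vseg_error("cannot aggregate an empty record list", "vseg_empty_input")
  stopifnot(all(vapply(records, inherits, TRUE, "metrics_record")))
  get <- function(f) vapply(records, function(r) r[[f]], numeric(1))
  regions <- unique(vapply(records, function(r) as.character(r$region),
                           character(1)))
  metrics_record(acc = mean(get("acc")), sn = mean(get("sn")),
                 sp = mean(get("sp")), image_id = "average",
                 region = paste(regions, collapse = "+"))
}

#' @export
as.data.frame.metrics_record <- function(x, ...) {
  data.frame(image_id = x$image_id, acc = x$acc, sn = x$sn, sp = x$sp,
             auc = x$auc, eval_region = x$region, stringsAsFactors = FALSE)
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf("metrics [%s, region=%s]: Acc=%.3f Sn=%.3f Sp=%.3f AUC=%.3f\n",
              x$image_id, x$region,
              x$acc, x$sn, x$sp, x$auc))
  invisible(x)
}

#' Write per-image and average metrics to CSV and JSON
#'
#' @param records list of `metrics_record` objects (per image).
#' @param path output path without extension, or ending in `.csv`/`.json`
#'   to write a single format.
#' @return invisibly, the combined data frame (per-image rows plus one
#'   average row).
#' @export
write_metrics <- function(records, path) {
  avg <- aggregate_metrics(records)
  df <- do.call(rbind, lapply(c(records, list(avg)), as.data.frame))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
    jsonlite::write_json(df, paste0(path, ".json"), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(df)
}

#' Published benchmark scores shipped with the package
#'
#' Per-image accuracy/sensitivity/specificity reported for this method on
#' the 20 DRIVE and 20 STARE test images (`reference_scores.csv`), and the
#' dataset-level summary rows (`reference_summary.csv`) used to validate
#' the metric arithmetic. These are reported values, not outputs of this
#' implementation.
#'
#' @param which `"per_image"` or `"summary"`.
#' @return a data frame.
#' @export
reference_scores <- function(which = c("per_image", "summary")) {
  which <- match.arg(which)
  f <- if (which == "per_image") "reference_scores.csv" else "reference_summary.csv"
  utils::read.csv(system.file("extdata", f, package = "vesselseg",
                              mustWork = TRUE), stringsAsFactors = FALSE)
}
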