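# Area-based denoising: thresholding leaves small isolated specks that are
# noise, not vasculature; genuine vessel segments are large and connected.

#' Label connected components of a binary mask
#'
#' @param mask 0/1 matrix.
#' @param connectivity 4 or 8 (default 8; thin diagonal vessels fragment
#'   under 4-connectivity).
#' @return object of class `component_labeling`: integer matrix `labels`
#'   (0 = background, components numbered 1..K), integer vector `sizes`
#'   (pixels per component), and the connectivity used.
#' @export
label_components <- function(mask, connectivity = 8) {
  assert_mask(mask)
  if (!connectivity %in% c(4, 8))
    vseg_error("connectivity must be 4 or 8", "vseg_bad_input")
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask == 1L)
  labels <- matrix(0L, nr, nc)
  if (length(fg) == 0)
    return(structure(list(labels = labels, sizes = integer(0),
                          connectivity = connectivity),
                     class = "component_labeling"))
  id <- matrix(0L, nr, nc)
  id[fg] <- seq_along(fg)
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- list()
  rc <- arrayInd(fg, c(nr, nc))
  for (o in offs) {
    r2 <- rc[, 1] + o[1]; c2 <- rc[, 2] + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- id[cbind(r2[ok], c2[ok])]
    hit <- nb > 0L
    edges[[length(edges) + 1L]] <- cbind(id[fg][ok][hit], nb[hit])
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(em) && nrow(em) > 0)
    g <- igraph::add_edges(g, t(em))
  memb <- igraph::components(g)$membership
  labels[fg] <- as.integer(memb)
  structure(list(labels = labels,
                 sizes = tabulate(memb),
                 connectivity = connectivity),
            class = "component_labeling")
}

#' Remove small connected components from a binary mask
#'
#' Deletes every connected component whose area is less than or equal to
#' `max_removed_area` pixels (default 30: specks of up to 30 connected
#' pixels are treated as background noise, anything larger is kept as
#' vessel). Never adds a pixel; idempotent.
#'
#' @param mask 0/1 matrix.
#' @param max_removed_area largest component area, in pixels, that is
#'   still removed (default 30).
#' @param connectivity 4 or 8 (default 8).
#' @return filtered 0/1 matrix.
#' @export
area_filter <- function(mask, max_removed_area = 30, connectivity = 8) {
  assert_mask(mask)
  if (max_removed_area < 0)
    vseg_error("max_removed_area must be >= 0", "vseg_bad_input")
  cc <- label_components(mask, connectivity)
  if (length(cc$sizes) == 0) return(mask)
  keep <- which(cc$sizes > max_removed_area)
  out <- (cc$labels %in% keep) * 1L
  matrix(out, nrow(mask), ncol(mask))
}
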