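#' Detect round cells in a field of view
#'
#' Thresholds a Gaussian-smoothed max projection of the chosen channel
#' (Otsu by default, so segmentation is invariant to intensity rescaling),
#' fills holes, labels connected components, and drops components below a
#' minimum area. Each detected region becomes one candidate cell ROI with
#' centroid, area, roundness (`4*pi*area / perimeter^2`), and a 0-based
#' half-open bounding box.
#'
#' @param stack An [image_stack()].
#' @param channel Channel to segment on; default `"cell"` (membrane/phase
#'   proxy).
#' @param threshold_method `"otsu"` or `"quantile"` (upper-quartile based).
#' @param min_area_um2 Minimum component area in um^2.
#' @param smooth_sigma_px Gaussian pre-smoothing sigma in px.
#' @return A tibble with one row per ROI: `cell_id`, `mask` (list column of
#'   full-frame logical matrices), bounding box, centroid (0-based px),
#'   `area_px`, `area_um2`, `equiv_diameter_um`, `roundness`, and the
#'   screening flags `round_pass`, `single_parb_pass` (initially `NA`).
#' @export
detect_cells <- function(stack, channel = "cell",
                         threshold_method = c("otsu", "quantile"),
                         min_area_um2 = 1, smooth_sigma_px = 1) {
  threshold_method <- match.arg(threshold_method)
  img <- max_project(stack, channel)
  if (max(img) <= 0) return(empty_roi_table())
  sm <- blur2d(img, smooth_sigma_px)
  sm_norm <- sm / max(sm)  # scale invariance
  thr <- switch(threshold_method,
    otsu = otsu_threshold(sm_norm),
    quantile = {
      q <- stats::quantile(sm_norm, c(0.25, 0.99))
      mean(q)
    })
  mask <- sm_norm > thr
  if (!any(mask)) return(empty_roi_table())
  mask <- EBImage::fillHull(EBImage::Image(mask * 1))
  lab <- EBImage::bwlabel(mask)
  feats <- EBImage::computeFeatures.shape(lab)
  if (is.null(dim(feats))) feats <- matrix(feats, nrow = 1,
                                           dimnames = list(NULL, names(feats)))
  labm <- EBImage::imageData(lab)
  px_area_um2 <- (stack$pixel_size / 1000)^2
  min_area_px <- min_area_um2 / px_area_um2

  rows <- list()
  grids <- coord_grids(dim(labm))
  k <- 0L
  for (i in seq_len(nrow(feats))) {
    area <- feats[i, "s.area"]
    if (area < min_area_px) next
    m <- labm == i
    perim <- feats[i, "s.perimeter"]
    roundness <- min(4 * pi * area / max(perim, 1)^2, 1)
    k <- k + 1L
    xs <- grids$x[m]; ys <- grids$y[m]
    rows[[k]] <- tibble::tibble(
      cell_id = k,
      mask = list(m),
      bbox_x0 = min(xs), bbox_x1 = max(xs) + 1L,
      bbox_y0 = min(ys), bbox_y1 = max(ys) + 1L,
      centroid_x_px = mean(xs), centroid_y_px = mean(ys),
      area_px = as.numeric(area),
      area_um2 = area * px_area_um2,
      equiv_diameter_um = 2 * sqrt(area * px_area_um2 / pi),
      roundness = roundness,
      round_pass = NA, single_parb_pass = NA)
  }
  if (k == 0L) return(empty_roi_table())
  dplyr::bind_rows(rows)
}

empty_roi_table <- function() {
  tibble::tibble(cell_id = integer(0), mask = list(),
                 bbox_x0 = integer(0), bbox_x1 = integer(0),
                 bbox_y0 = integer(0), bbox_y1 = integer(0),
                 centroid_x_px = numeric(0), centroid_y_px = numeric(0),
                 area_px = numeric(0), area_um2 = numeric(0),
                 equiv_diameter_um = numeric(0), roundness = numeric(0),
                 round_pass = logical(0), single_parb_pass = logical(0))
}

#' Build an ROI row from a binary mask
#'
#' Convenience constructor for toy masks in tests and for externally
#' provided segmentations.
#'
#' @param mask Logical matrix (one connected component).
#' @param pixel_size nm/px.
#' @param cell_id Identifier.
#' @return A one-row ROI tibble matching [detect_cells()] output.
#' @export
roi_from_mask <- function(mask, pixel_size = 65.35, cell_id = 1L) {
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  feats <- EBImage::computeFeatures.shape(lab)
  if (is.null(dim(feats))) feats <- matrix(feats, nrow = 1,
                                           dimnames = list(NULL, names(feats)))
  if (nrow(feats) > 1) stop("mask must be a single connected component", call. = FALSE)
  grids <- coord_grids(dim(mask))
  xs <- grids$x[mask]; ys <- grids$y[mask]
  area <- sum(mask)
  px_area_um2 <- (pixel_size / 1000)^2
  tibble::tibble(
    cell_id = cell_id, mask = list(mask),
    bbox_x0 = min(xs), bbox_x1 = max(xs) + 1L,
    bbox_y0 = min(ys), bbox_y1 = max(ys) + 1L,
    centroid_x_px = mean(xs), centroid_y_px = mean(ys),
    area_px = as.numeric(area), area_um2 = area * px_area_um2,
    equiv_diameter_um = 2 * sqrt(area * px_area_um2 / pi),
    roundness = min(4 * pi * area / max(feats[1, "s.perimeter"], 1)^2, 1),
    round_pass = NA, single_parb_pass = NA)
}

#' Screen ROIs by roundness
#'
#' Keeps ROIs whose roundness (`4*pi*area/perimeter^2`) is at least
#' `roundness_min`, mirroring the simple roundness criterion used to reject
#' thresholding artifacts among hand-picked round cells. A filter: output
#' is a subset of input with order preserved, and applying it twice equals
#' applying it once.
#'
#' @param rois ROI tibble from [detect_cells()].
#' @param roundness_min Threshold in (0, 1]; default 0.85.
#' @return The retained rows with `round_pass = TRUE`.
#' @export
screen_round <- function(rois, roundness_min = 0.85) {
  if (!is.numeric(roundness_min) || roundness_min <= 0 || roundness_min > 1) {
    stop("`roundness_min` must lie in (0, 1]", call. = FALSE)
  }
  out <- dplyr::filter(rois, .data$roundness >= roundness_min)
  out$round_pass <- rep(TRUE, nrow(out))
  out
}

#' Apply the single-chromosome (single ParB focus) selection rule
#'
#' A cell is accepted only if exactly one ParB focus appears in the
#' maximum-intensity projection within its mask — the rule that separates
#' replication-halted single-chromosome cells from multi-origin ones.
#'
#' @param rois ROI tibble.
#' @param parb_projection Max-projected ParB image (matrix), e.g.
#'   `max_project(stack, "ParB")`.
#' @param pixel_size nm/px.
#' @param psf_sigma_nm PSF sigma in nm for focus detection.
#' @param min_prominence Detection prominence in robust-noise units.
#' @return `rois` with `single_parb_pass` filled in.
#' @export
select_single_chromosome <- function(rois, parb_projection, pixel_size = 65.35,
                                     psf_sigma_nm = 120, min_prominence = 5) {
  if (nrow(rois) == 0) return(rois)
  pass <- vapply(rois$mask, function(m) {
    f <- detect_foci(parb_projection, m, pixel_size = pixel_size,
                     psf_sigma_nm = psf_sigma_nm, min_prominence = min_prominence)
    nrow(f) == 1L
  }, logical(1))
  rois$single_parb_pass <- pass
  rois
}
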