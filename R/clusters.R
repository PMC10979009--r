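#' Decompose a nucleoid pattern into psf-limited spots
#'
#' Greedy matching pursuit with fixed-width Gaussians: repeatedly find the
#' brightest residual pixel, place a Gaussian of width `psf_sigma` at its
#' intensity-weighted sub-pixel position, and subtract, stopping when the
#' residual peak drops below `stop_criterion` times the robust (MAD-based)
#' noise or `max_spots` is reached. Amplitudes are then re-fit jointly by
#' non-negative least squares over the mask; if the joint refit fails the
#' greedy amplitudes are kept with a warning.
#'
#' @param image Numeric matrix (DNA channel projection).
#' @param mask Logical matrix, cell mask.
#' @param pixel_size nm/px.
#' @param psf_sigma_nm PSF sigma in nm (> 0); spot width is fixed to it.
#' @param stop_criterion Residual-peak stop threshold in noise units
#'   (default 3).
#' @param max_spots Safety cap on the number of spots (default 40).
#' @return A `spot_set`: tibble (`spot_id`, `x_px`, `y_px`, `amplitude`,
#'   `sigma_px`, `intensity`) with attributes `total_cell_signal`,
#'   `residual_norm` (per-iteration L2 norms), `stopping_reason`
#'   (`"below_noise"` or `"max_spots"`), `noise`, `pixel_size`.
#' @export
decompose_spots <- function(image, mask, pixel_size = 65.35, psf_sigma_nm = 120,
                            stop_criterion = 3, max_spots = 40L) {
  if (psf_sigma_nm <= 0) stop("`psf_sigma_nm` must be > 0", call. = FALSE)
  sigma_px <- psf_sigma_nm / pixel_size
  bgst <- mask_background(image, mask)
  w <- image - bgst$bg
  w[!mask | w < 0] <- 0
  total <- sum(w)
  noise <- bgst$noise

  d <- dim(image)
  resid <- w
  xs <- ys <- amps <- numeric(0)
  norms <- sqrt(sum(resid^2))
  reason <- "max_spots"
  w_half <- max(1L, as.integer(round(sigma_px)))
  # photon-normalized pixel-integrated template; amps are photon counts
  t_peak <- (2 * stats::pnorm(0.5 / sigma_px) - 1)^2

  for (k in seq_len(max_spots)) {
    pk <- which.max(resid)
    pv <- resid[pk]
    if (pv < stop_criterion * noise || pv <= 0) { reason <- "below_noise"; break }
    rc <- arrayInd(pk, d)
    pos <- centroid_position(
      resid[max(1, rc[1] - w_half):min(d[1], rc[1] + w_half),
            max(1, rc[2] - w_half):min(d[2], rc[2] + w_half), drop = FALSE],
      max(1, rc[1] - w_half), max(1, rc[2] - w_half))
    a <- pv / t_peak
    xs <- c(xs, pos[1]); ys <- c(ys, pos[2]); amps <- c(amps, a)
    resid <- resid - a * gauss_pixel_spot(d, pos[1], pos[2], sigma_px)
    resid[resid < 0] <- 0
    norms <- c(norms, sqrt(sum(resid^2)))
  }

  if (length(xs) == 0) {
    out <- tibble::tibble(spot_id = integer(0), x_px = numeric(0),
                          y_px = numeric(0), amplitude = numeric(0),
                          sigma_px = numeric(0), intensity = numeric(0))
    return(new_spot_set(out, total, norms, "below_noise", noise, pixel_size))
  }

  # joint NNLS amplitude refit on masked pixels, alternated with local
  # position re-refinement: greedy centroids are pulled toward bright
  # neighbors, and re-centering each spot on the residual that excludes
  # the other spots removes that bias (spurious spots then collapse to
  # zero amplitude in the next NNLS pass)
  midx <- which(mask)
  design <- function() {
    vapply(seq_along(xs), function(j) {
      gauss_pixel_spot(d, xs[j], ys[j], sigma_px)[midx]
    }, numeric(length(midx)))
  }
  refit_failed <- FALSE
  for (pass in 1:4) {
    A <- design()
    refit <- tryCatch(pracma::lsqnonneg(A, w[midx])$x, error = function(e) NULL)
    if (is.null(refit) || any(!is.finite(refit))) { refit_failed <- TRUE; break }
    amps <- refit
    norms <- c(norms, sqrt(sum((w[midx] - as.vector(A %*% amps))^2)))
    if (pass == 4) break
    # drop zero-amplitude spots, re-center each survivor on the residual
    # that excludes the other spots (wide window: the full spot), then
    # merge spots within one sigma of a stronger one: greedy ghosts
    # collapse onto the emitter they belong to
    live <- amps > 1e-8 * max(amps)
    xs <- xs[live]; ys <- ys[live]; amps <- amps[live]
    w_wide <- max(2L, as.integer(round(2 * sigma_px)))
    full_model <- matrix(0, d[1], d[2])
    comps <- lapply(seq_along(xs), function(j) {
      amps[j] * gauss_pixel_spot(d, xs[j], ys[j], sigma_px)
    })
    for (cmp in comps) full_model <- full_model + cmp
    for (j in seq_along(xs)) {
      rj <- w - (full_model - comps[[j]])
      rc <- c(round(ys[j]) + 1L, round(xs[j]) + 1L)
      rc <- pmin(pmax(rc, 1L), d)
      pos <- centroid_position(
        rj[max(1, rc[1] - w_wide):min(d[1], rc[1] + w_wide),
           max(1, rc[2] - w_wide):min(d[2], rc[2] + w_wide), drop = FALSE],
        max(1, rc[1] - w_wide), max(1, rc[2] - w_wide))
      xs[j] <- pos[1]; ys[j] <- pos[2]
    }
    ord <- order(-amps)
    merged_x <- merged_y <- merged_a <- numeric(0)
    for (j in ord) {
      hit <- FALSE
      if (length(merged_x)) {
        dj <- sqrt((merged_x - xs[j])^2 + (merged_y - ys[j])^2)
        k <- which(dj <= sigma_px)[1]
        if (!is.na(k)) {
          tot <- merged_a[k] + amps[j]
          merged_x[k] <- (merged_x[k] * merged_a[k] + xs[j] * amps[j]) / tot
          merged_y[k] <- (merged_y[k] * merged_a[k] + ys[j] * amps[j]) / tot
          merged_a[k] <- tot
          hit <- TRUE
        }
      }
      if (!hit) {
        merged_x <- c(merged_x, xs[j]); merged_y <- c(merged_y, ys[j])
        merged_a <- c(merged_a, amps[j])
      }
    }
    xs <- merged_x; ys <- merged_y; amps <- merged_a
  }
  if (refit_failed) {
    warning("joint NNLS amplitude refit failed; keeping greedy amplitudes",
            call. = FALSE)
  }

  keep <- amps > 1e-8 * max(amps)
  out <- tibble::tibble(
    spot_id = seq_len(sum(keep)),
    x_px = xs[keep], y_px = ys[keep],
    amplitude = amps[keep] * t_peak,   # peak counts
    sigma_px = sigma_px,
    intensity = amps[keep])            # photons

  new_spot_set(out, total, cummin(norms), reason, noise, pixel_size)
}

new_spot_set <- function(tbl, total, norms, reason, noise, pixel_size) {
  attr(tbl, "total_cell_signal") <- total
  attr(tbl, "residual_norm") <- norms
  attr(tbl, "stopping_reason") <- reason
  attr(tbl, "noise") <- noise
  attr(tbl, "pixel_size") <- pixel_size
  class(tbl) <- c("spot_set", class(tbl))
  tbl
}

#' Group spots into psf-linked clusters
#'
#' Single-linkage grouping: two spots belong to the same cluster when one
#' is within the linking radius of the other, directly or through a chain
#' of such neighbors, so neighboring clusters are always separated by a
#' distinguishable gap larger than the radius. "Within one psf" is
#' interpreted as the PSF full width at half maximum (2.355 sigma) by
#' default. Clusters are ranked by relative intensity (fraction of the
#' whole-cell signal); rank 1 is the primary cluster, ties broken by
#' proximity to the ParB focus when given, else by spot id.
#'
#' @param spots A `spot_set` from [decompose_spots()].
#' @param link_radius_nm Linking radius in nm; `NULL`/`NA` uses the PSF FWHM.
#' @param psf_sigma_nm PSF sigma used when `link_radius_nm` is `NULL`.
#' @param parb_focus Optional one-row tibble/list with `x_px`, `y_px` for
#'   deterministic tie-breaking.
#' @return Tibble: `cluster_id`, `n_spots`, `centroid_x_px`,
#'   `centroid_y_px`, `centroid_x_nm`, `centroid_y_nm`,
#'   `relative_intensity`, `rank`, `is_primary`, `spot_ids` (list).
#' @export
group_clusters <- function(spots, link_radius_nm = NULL, psf_sigma_nm = 120,
                           parb_focus = NULL) {
  px <- attr(spots, "pixel_size") %||% 65.35
  if (is.null(link_radius_nm) || is.na(link_radius_nm)) {
    link_radius_nm <- 2.355 * psf_sigma_nm
  }
  n <- nrow(spots)
  if (n == 0) {
    return(tibble::tibble(cluster_id = integer(0), n_spots = integer(0),
                          centroid_x_px = numeric(0), centroid_y_px = numeric(0),
                          centroid_x_nm = numeric(0), centroid_y_nm = numeric(0),
                          relative_intensity = numeric(0), rank = integer(0),
                          is_primary = logical(0), spot_ids = list()))
  }
  memb <- if (n == 1L) 1L else {
    pos_nm <- cbind(spots$x_px, spots$y_px) * px
    hc <- stats::hclust(stats::dist(pos_nm), method = "single")
    stats::cutree(hc, h = link_radius_nm)
  }
  total <- attr(spots, "total_cell_signal")
  if (is.null(total) || total <= 0) total <- sum(spots$intensity)

  cl <- lapply(sort(unique(memb)), function(g) {
    i <- which(memb == g)
    wt <- spots$intensity[i]
    cx <- sum(spots$x_px[i] * wt) / sum(wt)
    cy <- sum(spots$y_px[i] * wt) / sum(wt)
    tibble::tibble(n_spots = length(i),
                   centroid_x_px = cx, centroid_y_px = cy,
                   centroid_x_nm = cx * px, centroid_y_nm = cy * px,
                   relative_intensity = sum(wt) / total,
                   spot_ids = list(spots$spot_id[i]))
  })
  out <- dplyr::bind_rows(cl)
  tie_key <- if (!is.null(parb_focus)) {
    sqrt((out$centroid_x_px - parb_focus[["x_px"]])^2 +
         (out$centroid_y_px - parb_focus[["y_px"]])^2)
  } else {
    vapply(out$spot_ids, min, numeric(1))
  }
  ord <- order(-out$relative_intensity, tie_key)
  out <- out[ord, ]
  out$cluster_id <- seq_len(nrow(out))
  out$rank <- seq_len(nrow(out))
  out$is_primary <- out$rank == 1L
  dplyr::select(out, "cluster_id", "n_spots", dplyr::starts_with("centroid"),
                "relative_intensity", "rank", "is_primary", "spot_ids")
}

#' Cluster positions relative to the origin and backbone
#'
#' Adds, for every cluster, the Euclidean distance to the ParB/ori focus
#' (nm) and, when a backbone is supplied, the signed arc-length coordinate
#' of the cluster centroid on the profile axis.
#'
#' @param clusters Output of [group_clusters()].
#' @param parb_focus One-row tibble/list with `x_px`, `y_px`.
#' @param backbone Optional [fit_backbone()] result.
#' @param pixel_size nm/px.
#' @return `clusters` with `distance_to_ori_nm` (and `s_um` if backbone
#'   given); empty tibble stays empty.
#' @export
primary_cluster_stats <- function(clusters, parb_focus, backbone = NULL,
                                  pixel_size = 65.35) {
  if (nrow(clusters) == 0) {
    clusters$distance_to_ori_nm <- numeric(0)
    return(clusters)
  }
  clusters$distance_to_ori_nm <-
    sqrt((clusters$centroid_x_px - parb_focus[["x_px"]])^2 +
         (clusters$centroid_y_px - parb_focus[["y_px"]])^2) * pixel_size
  if (!is.null(backbone)) {
    th <- atan2(clusters$centroid_y_px - backbone$center_y_px,
                clusters$centroid_x_px - backbone$center_x_px)
    dth <- wrap_angle(th - backbone$ori_angle)
    sgn <- backbone$orientation_sign
    if (is.na(sgn)) sgn <- 1
    clusters$s_um <- sgn * backbone$radius_mean_px * dth *
      backbone$pixel_size / 1000
  }
  clusters
}

#' Fraction of signal within a radius of a point
#'
#' Background-subtracted integrated signal inside the Euclidean disc about
#' `origin` divided by the total within the mask; pixels count as inside
#' when their center lies in the disc. Generic over a measured image
#' (matrix method) and the generator's ground truth
#' ([truth_fraction_within_radius()] for `sim_truth` objects).
#'
#' @param x Numeric matrix or `sim_truth`.
#' @param ... Method arguments.
#' @return Fraction in \[0, 1\].
#' @export
fraction_within_radius <- function(x, ...) UseMethod("fraction_within_radius")

#' @rdname fraction_within_radius
#' @param mask Logical matrix.
#' @param origin_xy_px `(x, y)` 0-based position of the reference point.
#' @param radius_nm Disc radius in nm (default 500).
#' @param pixel_size nm/px.
#' @export
fraction_within_radius.matrix <- function(x, mask, origin_xy_px,
                                          radius_nm = 500,
                                          pixel_size = 65.35, ...) {
  if (radius_nm <= 0) stop("`radius_nm` must be > 0", call. = FALSE)
  bgst <- mask_background(x, mask)
  w <- x - bgst$bg
  w[!mask | w < 0] <- 0
  grids <- coord_grids(dim(x))
  d_nm <- sqrt((grids$x - origin_xy_px[1])^2 +
               (grids$y - origin_xy_px[2])^2) * pixel_size
  tot <- sum(w)
  if (tot <= 0) return(0)
  sum(w[d_nm <= radius_nm]) / tot
}

#' @rdname fraction_within_radius
#' @export
fraction_within_radius.sim_truth <- function(x, radius_nm = 500,
                                             origin_xy_px = x$ori_xy_px, ...) {
  truth_fraction_within_radius(x, radius_nm = radius_nm,
                               origin_xy_px = origin_xy_px)
}
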