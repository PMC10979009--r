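#' Fit the annular backbone of a crescent/toroidal chromosome
#'
#' Places an annular coordinate system over the chromosome arc: the center
#' is the intensity-weighted centroid of the above-Otsu DNA pixels refined
#' by a least-squares circle fit (algebraic Kasa fit plus one Gauss-Newton
#' step), the radius is the intensity-weighted mean radius per angular
#' bin, and the ori anchor is the angle of the ParB focus about the
#' center. Angular bins containing chromosome-classified pixels form the
#' angular support. Cells whose signal does not spread over at least
#' `min_support_bins` bins, or whose fitted circle is implausible for the
#' mask, are rejected with a `shape_not_arclike` error condition,
#' mirroring the screening out of non-arc patterns.
#'
#' @param dna_image Numeric matrix, the DNA channel (max projection).
#' @param mask Logical matrix, the cell mask.
#' @param parb_focus One-row tibble/list with `x_px`, `y_px` (the ori
#'   proxy).
#' @param pixel_size nm/px.
#' @param n_angle_bins Number of angular bins (default 72, i.e. 5 deg).
#' @param min_support_bins Minimum bins with chromosome signal (default 3).
#' @return An object of class `backbone`: center, per-bin radius and
#'   intensity with support flags, mean radius, ori angle, background
#'   statistics, and the mask.
#' @export
fit_backbone <- function(dna_image, mask, parb_focus, pixel_size = 65.35,
                         n_angle_bins = 72L, min_support_bins = 3L) {
  bgst <- mask_background(dna_image, mask)
  w <- dna_image - bgst$bg
  w[!mask | w < 0] <- 0
  sig <- mask & (dna_image > bgst$otsu)
  if (sum(sig) < 5) {
    stop_shape_not_arclike("fewer than 5 chromosome pixels above threshold")
  }
  grids <- coord_grids(dim(dna_image))
  sx <- grids$x[sig]; sy <- grids$y[sig]; sw <- w[sig]

  ctr <- fit_circle(sx, sy, sw)
  mask_r <- sqrt(sum(mask) / pi)
  if (!is.finite(ctr$r) || ctr$r < 1.5 || ctr$r > 3 * mask_r) {
    stop_shape_not_arclike(sprintf("circle fit degenerate (radius %.1f px)", ctr$r))
  }

  theta <- atan2(sy - ctr$cy, sx - ctr$cx)
  r <- sqrt((sx - ctr$cx)^2 + (sy - ctr$cy)^2)
  # an annular pattern is thin relative to its radius; compact blobs fit a
  # small circle through their interior and show a large radial spread
  r_w <- sum(sw * r) / sum(sw)
  spread <- sqrt(sum(sw * (r - r_w)^2) / sum(sw)) / r_w
  if (spread > 0.35) {
    stop_shape_not_arclike(sprintf(
      "radial spread %.2f of the fitted annulus is too large for an arc",
      spread))
  }
  edges <- seq(-pi, pi, length.out = n_angle_bins + 1L)
  bin <- findInterval(theta, edges, rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L; bin[bin > n_angle_bins] <- n_angle_bins

  I_bin <- rep(0, n_angle_bins)
  r_bin <- rep(NA_real_, n_angle_bins)
  agg_w <- rowsum(sw, bin)
  agg_wr <- rowsum(sw * r, bin)
  at <- as.integer(rownames(agg_w))
  I_bin[at] <- agg_w[, 1]
  r_bin[at] <- agg_wr[, 1] / agg_w[, 1]
  support <- I_bin > 0

  if (sum(support) < min_support_bins) {
    stop_shape_not_arclike(sprintf("signal confined to %d angular bin(s)",
                                   sum(support)))
  }

  ori_angle <- atan2(parb_focus[["y_px"]] - ctr$cy, parb_focus[["x_px"]] - ctr$cx)
  r_mean <- sum(I_bin[support] * r_bin[support]) / sum(I_bin[support])

  structure(list(
    center_x_px = ctr$cx, center_y_px = ctr$cy,
    radius_mean_px = r_mean,
    bins = tibble::tibble(
      angle = (edges[-1] + edges[-length(edges)]) / 2,
      radius_px = r_bin, intensity = I_bin, support = support),
    angular_coverage_deg = sum(support) * 360 / n_angle_bins,
    ori_angle = ori_angle,
    orientation_sign = NA_real_,
    pixel_size = pixel_size,
    background = bgst,
    mask = mask
  ), class = "backbone")
}

stop_shape_not_arclike <- function(msg) {
  cond <- structure(class = c("shape_not_arclike", "error", "condition"),
                    list(message = msg, call = NULL))
  stop(cond)
}

# Weighted Kasa circle fit + Gauss-Newton refinement of the geometric fit
# (the algebraic fit underestimates the radius for short, wide arcs).
fit_circle <- function(x, y, w, gn_iters = 8L) {
  w <- w / sum(w)
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  WA <- A * sqrt(w); Wb <- b * sqrt(w)
  sol <- tryCatch(qr.solve(WA, Wb), error = function(e) NULL)
  if (is.null(sol)) return(list(cx = NA_real_, cy = NA_real_, r = NA_real_))
  cx <- sol[1]; cy <- sol[2]
  r <- sqrt(max(sol[3] + cx^2 + cy^2, 0))
  for (iter in seq_len(gn_iters)) {
    dx <- x - cx; dy <- y - cy
    di <- sqrt(dx^2 + dy^2)
    di[di < 1e-9] <- 1e-9
    res <- di - r
    J <- cbind(-dx / di, -dy / di, -1)
    WJ <- J * sqrt(w); Wres <- res * sqrt(w)
    step <- tryCatch(qr.solve(WJ, -Wres), error = function(e) c(0, 0, 0))
    cx <- cx + step[1]; cy <- cy + step[2]; r <- r + step[3]
  }
  list(cx = cx, cy = cy, r = r)
}

#' Sample channel intensities along the backbone
#'
#' Converts every mask pixel to a signed arc-length coordinate
#' `s = r_mean * (theta - ori_angle)` measured from the ParB/ori anchor,
#' integrates each channel's background-subtracted intensity over annular
#' wedges of width `bin_um` in both angular directions, and divides by the
#' bin arc length ("per unit annular section"). Bins beyond the observed
#' signal, up to `representative_length_um`, are kept as `NA` so that
#' profiles of different cells share a common axis. Run [align_and_flip()]
#' afterwards to obtain the one-sided, ori-anchored profile.
#'
#' @param stack An [image_stack()].
#' @param backbone A [fit_backbone()] result.
#' @param channels Channel labels to sample (default all but `"cell"`).
#' @param bin_um Bin width in um (default 0.13, i.e. ~2 px).
#' @param representative_length_um Common profile length in um (default
#'   3.5).
#' @return A `contour_profile` tibble: `s_um` (signed bin centers),
#'   `channel`, `raw_per_um`, `fold_increase`, with profile metadata in
#'   attributes.
#' @export
profile_along_backbone <- function(stack, backbone, channels = NULL,
                                   bin_um = 0.13,
                                   representative_length_um = 3.5) {
  if (bin_um <= 0) stop("`bin_um` must be > 0", call. = FALSE)
  if (representative_length_um <= bin_um) {
    stop("`representative_length_um` must exceed `bin_um`", call. = FALSE)
  }
  if (is.null(channels)) channels <- setdiff(stack$channel_labels, "cell")
  px <- stack$pixel_size
  mask <- backbone$mask
  grids <- coord_grids(dim(mask))
  idx <- which(mask)
  theta <- atan2(grids$y[idx] - backbone$center_y_px,
                 grids$x[idx] - backbone$center_x_px)
  dtheta <- wrap_angle(theta - backbone$ori_angle)
  s_um <- backbone$radius_mean_px * dtheta * px / 1000

  n_bins <- ceiling(representative_length_um / bin_um)
  edges <- seq(-n_bins * bin_um, n_bins * bin_um, by = bin_um)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  # tent-kernel deposition onto the two nearest bin centers: smooths the
  # angular quantization of whole pixels into wedges
  pos <- (s_um - centers[1]) / bin_um
  lo <- floor(pos)
  frac <- pos - lo
  covered <- tabulate(findInterval(s_um, edges, rightmost.closed = TRUE),
                      nbins = length(centers)) > 0
  deposit <- function(wch) {
    raw <- numeric(length(centers))
    for (k in 0:1) {
      b <- lo + k + 1L
      ok <- b >= 1L & b <= length(centers)
      wt <- if (k == 0) 1 - frac else frac
      if (any(ok)) {
        agg <- rowsum((wch * wt)[ok], b[ok])
        at <- as.integer(rownames(agg))
        raw[at] <- raw[at] + agg[, 1]
      }
    }
    raw
  }

  out <- lapply(channels, function(ch) {
    img <- max_project(stack, ch)
    bgst <- mask_background(img, mask)
    wch <- img[idx] - bgst$bg
    wch[wch < 0] <- 0
    raw <- deposit(wch) / bin_um
    raw[!covered] <- NA_real_
    tibble::tibble(s_um = centers, channel = ch, raw_per_um = raw)
  })
  prof <- dplyr::bind_rows(out)
  prof <- add_fold_increase(prof)
  new_contour_profile(prof,
                      bin_um = bin_um,
                      representative_length_um = representative_length_um,
                      radius_mean_px = backbone$radius_mean_px,
                      pixel_size = px,
                      two_sided = TRUE,
                      orientation_sign = NA_real_,
                      dna_channel = if ("DNA" %in% channels) "DNA" else channels[1])
}

wrap_angle <- function(a) {
  ((a + pi) %% (2 * pi)) - pi
}

add_fold_increase <- function(prof) {
  dplyr::mutate(
    dplyr::group_by(prof, .data$channel),
    fold_increase = {
      m <- mean(.data$raw_per_um, na.rm = TRUE)
      if (is.finite(m) && m > 0) .data$raw_per_um / m else .data$raw_per_um * NA
    }) |> dplyr::ungroup()
}

new_contour_profile <- function(prof, ...) {
  attrs <- list(...)
  for (nm in names(attrs)) attr(prof, nm) <- attrs[[nm]]
  class(prof) <- c("contour_profile", class(prof))
  prof
}

#' Orient a profile so the chromosome extends toward positive lengths
#'
#' Crescents may lie clockwise or counterclockwise about their center, so
#' the two-sided profile is flipped such that the total DNA intensity on
#' the positive side is maximal, then truncated to the positive side.
#' Applying the function to an already one-sided profile is a no-op
#' (involution-safe).
#'
#' @param profile A `contour_profile` from [profile_along_backbone()].
#' @return A one-sided `contour_profile` starting at `s = 0` (ori) with
#'   `fold_increase` recomputed over observed bins and
#'   `orientation_sign` recorded.
#' @export
align_and_flip <- function(profile) {
  if (!isTRUE(attr(profile, "two_sided"))) return(profile)
  dna <- attr(profile, "dna_channel")
  dsub <- profile[profile$channel == dna, ]
  pos <- sum(dsub$raw_per_um[dsub$s_um > 0], na.rm = TRUE)
  neg <- sum(dsub$raw_per_um[dsub$s_um < 0], na.rm = TRUE)
  sign <- if (pos >= neg) 1 else -1
  out <- profile
  out$s_um <- sign * out$s_um
  out <- out[out$s_um > 0, ]
  out <- out[order(out$channel, out$s_um), ]
  out <- add_fold_increase(out)
  new_contour_profile(out,
                      bin_um = attr(profile, "bin_um"),
                      representative_length_um = attr(profile, "representative_length_um"),
                      radius_mean_px = attr(profile, "radius_mean_px"),
                      pixel_size = attr(profile, "pixel_size"),
                      two_sided = FALSE,
                      orientation_sign = sign,
                      dna_channel = dna)
}

#' Estimate an exponential decay length from a profile
#'
#' Weighted least squares of `log(fold_increase)` against arc length,
#' returning the decay length (um). Used to quantify the gradual DNA
#' decrease from ori toward ter. Convolution with the PSF/ribbon kernel
#' leaves the log-slope of an exponential unchanged in the interior but
#' depresses the bins within about one blur width of the chromosome tips,
#' so those edges are excluded from the fit by default.
#'
#' @param profile One-sided `contour_profile`.
#' @param channel Channel to fit (default the DNA channel).
#' @param floor_frac Bins below this fraction of the profile maximum are
#'   excluded and define the far end of the chromosome (default 0.05).
#' @param edge_trim_um Arc length excluded at the ori tip (default 0.45,
#'   about two PSF-plus-ribbon widths).
#' @param tail_trim_um Arc length excluded before the far tip (default
#'   0.25).
#' @return Decay length in um (`NA` if fewer than 3 usable bins).
#' @export
estimate_decay_length <- function(profile, channel = NULL, floor_frac = 0.05,
                                  edge_trim_um = 0.45, tail_trim_um = 0.25) {
  if (is.null(channel)) channel <- attr(profile, "dna_channel")
  p <- profile[profile$channel == channel & !is.na(profile$fold_increase), ]
  if (nrow(p) == 0) return(NA_real_)
  s_max <- max(p$s_um[p$fold_increase > floor_frac * max(p$fold_increase)])
  p <- p[p$s_um >= edge_trim_um & p$s_um <= s_max - tail_trim_um &
           p$fold_increase > 0, ]
  if (nrow(p) < 3) return(NA_real_)
  fit <- stats::lm(log(fold_increase) ~ s_um, data = p, weights = p$fold_increase)
  slope <- stats::coef(fit)[["s_um"]]
  if (slope >= 0) return(Inf)
  -1 / slope
}
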