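#' Detect psf-limited fluorescent foci at sub-pixel precision
#'
#' Finds local maxima above a robust prominence threshold inside a cell
#' mask, merges duplicate maxima closer than one PSF sigma (keeping the
#' brighter), and refines each to sub-pixel position; refined positions
#' that land within 1.5 PSF sigma of a brighter focus are suppressed as
#' duplicates of the same emitter. Refinement uses the
#' intensity-weighted centroid (default) or a least-squares 2D Gaussian
#' fit over a window of half-width `2*psf_sigma`; the local background is
#' the median of the window's border ring. Integrated intensity is the
#' background-subtracted window sum, and `fraction_of_cell_signal` divides
#' it by the background-subtracted total over the mask, so fractions are
#' invariant to intensity rescaling.
#'
#' @param image Numeric matrix (one channel, one plane or a projection).
#' @param mask Logical matrix, same shape, the cell mask.
#' @param pixel_size nm/px.
#' @param psf_sigma_nm PSF sigma in nm (> 0).
#' @param min_prominence Threshold above background in robust-noise (MAD)
#'   units; default 5.
#' @param method `"centroid"` or `"gaussfit"`.
#' @return Tibble: `x_px`, `y_px` (0-based sub-pixel), `x_nm`, `y_nm`,
#'   `peak_value`, `intensity`, `fraction_of_cell_signal`, sorted by
#'   decreasing intensity.
#' @export
detect_foci <- function(image, mask, pixel_size = 65.35, psf_sigma_nm = 120,
                        min_prominence = 5, method = c("centroid", "gaussfit")) {
  method <- match.arg(method)
  if (!is.numeric(psf_sigma_nm) || psf_sigma_nm <= 0) {
    stop("`psf_sigma_nm` must be > 0", call. = FALSE)
  }
  if (!all(dim(image) == dim(mask))) {
    stop("`image` and `mask` dimensions differ", call. = FALSE)
  }
  sigma_px <- psf_sigma_nm / pixel_size
  stats_bg <- mask_background(image, mask)
  thr <- stats_bg$bg + min_prominence * stats_bg$noise

  cand <- local_maxima(image, mask, thr)
  if (nrow(cand) == 0) return(empty_foci_table())
  cand <- merge_close_maxima(cand, min_sep_px = sigma_px)

  w_half <- max(2L, as.integer(round(2 * sigma_px)))
  total <- sum(image[mask] - stats_bg$bg)
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    refine_focus(image, cand$row[i], cand$col[i], w_half, method, sigma_px)
  })
  out <- dplyr::bind_rows(rows)
  # refined positions of distinct integer maxima can collapse onto one
  # spot; suppress duplicates within 1.5 sigma, keeping the brighter
  # (mutual centroid pull draws genuine pairs no closer than ~0.6 of
  # their true separation, so resolvable spots survive)
  out <- out[order(-out$intensity), ]
  if (nrow(out) > 1) {
    keep <- logical(nrow(out))
    keep[1] <- TRUE
    for (i in 2:nrow(out)) {
      kept <- out[keep, , drop = FALSE]
      d <- sqrt((kept$x_px - out$x_px[i])^2 + (kept$y_px - out$y_px[i])^2)
      keep[i] <- all(d > 1.5 * sigma_px)
    }
    out <- out[keep, , drop = FALSE]
  }
  out$x_nm <- out$x_px * pixel_size
  out$y_nm <- out$y_px * pixel_size
  out$fraction_of_cell_signal <-
    if (total > 0) pmin(pmax(out$intensity / total, 0), 1) else 0
  out <- out[order(-out$intensity), ]
  tibble::as_tibble(out)
}

empty_foci_table <- function() {
  tibble::tibble(x_px = numeric(0), y_px = numeric(0), peak_value = numeric(0),
                 intensity = numeric(0), x_nm = numeric(0), y_nm = numeric(0),
                 fraction_of_cell_signal = numeric(0))
}

# 8-neighborhood local maxima inside mask, above threshold.
local_maxima <- function(image, mask, thr) {
  d <- dim(image)
  pad <- matrix(-Inf, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- image
  ctr <- pad[2:(d[1] + 1), 2:(d[2] + 1)]
  is_max <- matrix(TRUE, d[1], d[2])
  for (dy in -1:1) {
    for (dx in -1:1) {
      if (dx == 0 && dy == 0) next
      nb <- pad[(2 + dy):(d[1] + 1 + dy), (2 + dx):(d[2] + 1 + dx)]
      is_max <- is_max & (ctr >= nb)
    }
  }
  sel <- which(is_max & mask & image > thr, arr.ind = TRUE)
  tibble::tibble(row = sel[, 1], col = sel[, 2],
                 value = image[sel])
}

# Greedy merge: visit maxima brightest-first, drop any within min_sep of a kept one.
merge_close_maxima <- function(cand, min_sep_px) {
  cand <- cand[order(-cand$value), ]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1L) { keep[1] <- TRUE; next }
    kept <- cand[keep, , drop = FALSE]
    d <- sqrt((kept$row - cand$row[i])^2 + (kept$col - cand$col[i])^2)
    keep[i] <- all(d > min_sep_px)
  }
  cand[keep, , drop = FALSE]
}

refine_focus <- function(image, row, col, w_half, method, sigma_px) {
  d <- dim(image)
  r0 <- max(1L, row - w_half); r1 <- min(d[1], row + w_half)
  c0 <- max(1L, col - w_half); c1 <- min(d[2], col + w_half)
  win <- image[r0:r1, c0:c1]
  border <- c(win[1, ], win[nrow(win), ], win[, 1], win[, ncol(win)])
  bg <- stats::median(border)
  wsub <- win - bg
  pos <- if (method == "centroid") {
    centroid_position(wsub, r0, c0)
  } else {
    gaussfit_position(wsub, r0, c0, sigma_px)
  }
  tibble::tibble(x_px = pos[1], y_px = pos[2],
                 peak_value = image[row, col],
                 intensity = sum(wsub))
}

centroid_position <- function(wsub, r0, c0) {
  w <- pmax(wsub, 0)
  tot <- sum(w)
  if (tot <= 0) {
    return(c(c0 - 1 + (ncol(wsub) - 1) / 2, r0 - 1 + (nrow(wsub) - 1) / 2))
  }
  xs <- (c0 - 1) + (seq_len(ncol(wsub)) - 1)  # 0-based
  ys <- (r0 - 1) + (seq_len(nrow(wsub)) - 1)
  c(sum(w %*% xs) / tot, sum(ys %*% w) / tot)
}

gaussfit_position <- function(wsub, r0, c0, sigma_px) {
  init <- centroid_position(wsub, r0, c0)
  xs <- (c0 - 1) + (seq_len(ncol(wsub)) - 1)
  ys <- (r0 - 1) + (seq_len(nrow(wsub)) - 1)
  X <- matrix(rep(xs, each = nrow(wsub)), nrow(wsub))
  Y <- matrix(rep(ys, times = ncol(wsub)), nrow(wsub))
  a0 <- max(wsub)
  obj <- function(par) {
    mu <- par[1:2]; a <- par[3]; b <- par[4]
    model <- a * exp(-((X - mu[1])^2 + (Y - mu[2])^2) / (2 * sigma_px^2)) + b
    sum((model - wsub)^2)
  }
  fit <- stats::optim(c(init, a0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 500))
  fit$par[1:2]
}

#' Filter foci by their fraction of cell signal
#'
#' Removes detected spots that contain less than `min_fraction` of the
#' total signal present in the cell — the filter used to reject spurious
#' detections in low signal-to-noise channels such as sparse ter labels.
#' Idempotent; order preserved.
#'
#' @param foci Tibble with a `fraction_of_cell_signal` column.
#' @param min_fraction Retention threshold, default 0.15.
#' @return The retained rows.
#' @export
filter_foci_by_fraction <- function(foci, min_fraction = 0.15) {
  dplyr::filter(foci, .data$fraction_of_cell_signal >= min_fraction)
}

#' Euclidean distance between two foci in nm
#'
#' @param f1,f2 One-row tibbles (or lists) with `x_px`, `y_px`, and
#'   optionally `cell_id`; foci must belong to the same cell.
#' @param pixel_size nm/px.
#' @return Distance in nm.
#' @export
focus_distance <- function(f1, f2, pixel_size = 65.35) {
  id1 <- f1[["cell_id"]]; id2 <- f2[["cell_id"]]
  if (!is.null(id1) && !is.null(id2) && length(id1) && length(id2) &&
      !identical(id1, id2)) {
    stop("foci belong to different cells", call. = FALSE)
  }
  sqrt((f1[["x_px"]] - f2[["x_px"]])^2 + (f1[["y_px"]] - f2[["y_px"]])^2) *
    pixel_size
}

#' Per-cell focus counts and the ori:ter ratio
#'
#' Counts foci per cell and channel and forms the fluorescence-based
#' ori:ter ratio after fraction-filtering the ter channel. The default
#' ratio pools counts over all cells with at least one retained ter focus
#' (`sum(ori)/sum(ter)`); `per_cell = TRUE` instead averages per-cell
#' ratios.
#'
#' @param foci Tibble with columns `cell_id`, `channel`,
#'   `fraction_of_cell_signal`.
#' @param ori_channel,ter_channel Channel labels.
#' @param min_ter_fraction 15%-of-cell-signal filter applied to the ter
#'   channel before counting.
#' @param per_cell If `TRUE`, average per-cell ratios instead of pooling.
#' @return A list: `summary` (tibble of per-channel mean +/- sd counts),
#'   `per_cell` (tibble of per-cell counts), `ori_ter_ratio` (scalar, `NA`
#'   with a warning when no ter foci survive).
#' @export
count_and_ratio <- function(foci, ori_channel = "ParB", ter_channel = "ter",
                            min_ter_fraction = 0.15, per_cell = FALSE) {
  stopifnot(all(c("cell_id", "channel") %in% names(foci)))
  ter <- filter_foci_by_fraction(
    dplyr::filter(foci, .data$channel == ter_channel), min_ter_fraction)
  ori <- dplyr::filter(foci, .data$channel == ori_channel)
  kept <- dplyr::bind_rows(ori, ter)

  all_cells <- sort(unique(foci$cell_id))
  counts <- tidyr::complete(
    dplyr::count(kept, .data$cell_id, .data$channel),
    cell_id = all_cells, channel = c(ori_channel, ter_channel),
    fill = list(n = 0L))

  summary <- dplyr::summarise(
    dplyr::group_by(counts, .data$channel),
    mean_count = mean(.data$n), sd_count = stats::sd(.data$n),
    n_cells = dplyr::n_distinct(.data$cell_id), .groups = "drop")

  wide <- tidyr::pivot_wider(counts, names_from = "channel",
                             values_from = "n", values_fill = 0L)
  ter_n <- wide[[ter_channel]] %||% rep(0L, nrow(wide))
  ori_n <- wide[[ori_channel]] %||% rep(0L, nrow(wide))
  has_ter <- ter_n >= 1L
  ratio <- if (!any(has_ter)) {
    warning("no cells with a retained ter focus; ori:ter ratio undefined",
            call. = FALSE)
    NA_real_
  } else if (per_cell) {
    mean(ori_n[has_ter] / ter_n[has_ter])
  } else {
    sum(ori_n[has_ter]) / sum(ter_n[has_ter])
  }
  list(summary = summary, per_cell = wide, ori_ter_ratio = ratio)
}
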