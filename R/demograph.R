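#' Contrast of a contour profile
#'
#' Robust Michelson contrast `(q95 - q5) / (q95 + q5)` of the
#' fold-increase values (default), or the coefficient of variation
#' (`"cv"`, sd/mean). Both are invariant to intensity rescaling. Profiles
#' with fewer than two observed bins have undefined contrast (`NA` with a
#' warning).
#'
#' @param profile A one-sided `contour_profile`.
#' @param channel Channel to use (default the profile's DNA channel).
#' @param method `"michelson"` or `"cv"`.
#' @return Scalar contrast in \[0, 1) for `"michelson"`.
#' @export
profile_contrast <- function(profile, channel = NULL,
                             method = c("michelson", "cv")) {
  method <- match.arg(method)
  if (is.null(channel)) channel <- attr(profile, "dna_channel")
  v <- profile$fold_increase[profile$channel == channel]
  v <- v[!is.na(v)]
  if (length(v) < 2) {
    warning("fewer than 2 observed bins; contrast undefined", call. = FALSE)
    return(NA_real_)
  }
  if (method == "cv") {
    m <- mean(v)
    return(if (m > 0) stats::sd(v) / m else NA_real_)
  }
  q <- stats::quantile(v, c(0.05, 0.95), names = FALSE, type = 7)
  if (q[1] + q[2] <= 0) return(0)
  (q[2] - q[1]) / (q[2] + q[1])
}

#' Stack per-cell profiles into a demograph
#'
#' Rows are the fold-increase profiles of accepted cells on a shared
#' origin-anchored length axis, ordered top-to-bottom by decreasing
#' contrast (or another key). Bins a shorter chromosome does not reach are
#' missing values and are excluded from the column-wise mean profile (the
#' "average normalized intensity" trace).
#'
#' @param profiles List of one-sided `contour_profile` objects.
#' @param channel Channel to stack (default `"DNA"`).
#' @param order_by `"contrast"`, `"cv"`, or `"none"` (input order).
#' @param cell_ids Optional identifiers, defaults to list position.
#' @return A `demograph`: list with `matrix` (cells x bins), `s_um`,
#'   `cell_ids`, `order_key`, `mean_profile`, `channel`.
#' @export
build_demograph <- function(profiles, channel = "DNA",
                            order_by = c("contrast", "cv", "none"),
                            cell_ids = NULL) {
  order_by <- match.arg(order_by)
  if (length(profiles) == 0) stop("no profiles supplied", call. = FALSE)
  if (is.null(cell_ids)) cell_ids <- seq_along(profiles)
  grids <- lapply(profiles, function(p) p$s_um[p$channel == channel])
  ref <- grids[[1]]
  same <- vapply(grids, function(g) length(g) == length(ref) &&
                   max(abs(g - ref)) < 1e-9, logical(1))
  if (!all(same)) {
    stop("profiles sampled on different bin grids cannot be stacked",
         call. = FALSE)
  }
  mat <- t(vapply(profiles,
                  function(p) p$fold_increase[p$channel == channel],
                  numeric(length(ref))))
  key <- switch(order_by,
    contrast = vapply(profiles, function(p)
      suppressWarnings(profile_contrast(p, channel)), numeric(1)),
    cv = vapply(profiles, function(p)
      suppressWarnings(profile_contrast(p, channel, method = "cv")), numeric(1)),
    none = rev(seq_along(profiles)))
  drop <- is.na(key)
  if (any(drop)) {
    warning(sum(drop), " profile(s) with undefined ordering key dropped",
            call. = FALSE)
    mat <- mat[!drop, , drop = FALSE]
    cell_ids <- cell_ids[!drop]
    key <- key[!drop]
  }
  ord <- order(-key, cell_ids)
  structure(list(
    matrix = mat[ord, , drop = FALSE],
    s_um = ref,
    cell_ids = cell_ids[ord],
    order_key = key[ord],
    mean_profile = colMeans(mat, na.rm = TRUE),
    channel = channel
  ), class = "demograph")
}

#' @export
print.demograph <- function(x, ...) {
  cat(sprintf("<demograph> %s channel: %d cells x %d bins (%.2f-%.2f um)\n",
              x$channel, nrow(x$matrix), ncol(x$matrix),
              min(x$s_um), max(x$s_um)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a demograph into long format
#'
#' @param x A `demograph`.
#' @param ... Unused.
#' @return Tibble: `cell_id`, `row` (display order), `s_um`,
#'   `fold_increase`.
#' @method tidy demograph
#' @export
tidy.demograph <- function(x, ...) {
  n <- nrow(x$matrix)
  tibble::tibble(
    cell_id = rep(x$cell_ids, each = length(x$s_um)),
    row = rep(seq_len(n), each = length(x$s_um)),
    s_um = rep(x$s_um, times = n),
    fold_increase = as.vector(t(x$matrix)))
}

#' One-row demograph summary
#'
#' @param x A `demograph`.
#' @param ... Unused.
#' @return Tibble with cell/bin counts, bin range, and the peak location
#'   of the mean profile.
#' @method glance demograph
#' @export
glance.demograph <- function(x, ...) {
  tibble::tibble(
    channel = x$channel,
    n_cells = nrow(x$matrix),
    n_bins = ncol(x$matrix),
    s_max_um = max(x$s_um),
    mean_peak_s_um = x$s_um[which.max(x$mean_profile)],
    mean_peak_fold = max(x$mean_profile, na.rm = TRUE))
}

#' Plot a demograph heatmap
#'
#' @param object A `demograph`.
#' @param ... Unused.
#' @return A ggplot: cells (ordered by contrast) by arc length, colored by
#'   fold-increase.
#' @method autoplot demograph
#' @export
autoplot.demograph <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s_um, y = .data$row,
                                   fill = .data$fold_increase)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "fold-increase", na.value = "grey90") +
    ggplot2::labs(x = "distance from ori (µm)", y = "cell (by contrast)",
                  title = paste(object$channel, "demograph")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the population mean profile of a demograph
#'
#' @param demograph A `demograph`.
#' @return A ggplot of the average normalized intensity versus distance
#'   from the origin.
#' @export
plot_mean_profile <- function(demograph) {
  df <- tibble::tibble(s_um = demograph$s_um, fold = demograph$mean_profile)
  ggplot2::ggplot(df, ggplot2::aes(.data$s_um, .data$fold)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from ori (µm)",
                  y = "average fold-increase") +
    ggplot2::theme_minimal()
}
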