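#' Multichannel image stack
#'
#' Container for a multichannel, optionally z-stacked, fluorescence image
#' with a known physical pixel size. Pixels are stored as a 4-d numeric
#' array indexed `[y, x, z, channel]`. Coordinates reported by analysis
#' functions are 0-based with pixel centers at integer positions, so the
#' pixel stored at `pixels[1, 1, , ]` has center `(x, y) = (0, 0)`.
#'
#' @param pixels Numeric array. Accepted shapes: `[y, x]` (one plane, one
#'   channel), `[y, x, channel]`, or `[y, x, z, channel]`. Values must be
#'   finite and non-negative.
#' @param channel_labels Character vector naming the channels, e.g.
#'   `c("DNA", "ParB", "SMC", "cell")`.
#' @param pixel_size Physical pixel size in nm/px (default 65.35).
#' @param z_step Z-slice spacing in nm, or `NA` for single-plane stacks.
#'
#' @return An object of class `img_stack`: a list with elements `pixels`,
#'   `channel_labels`, `pixel_size`, `z_step`.
#' @export
image_stack <- function(pixels, channel_labels, pixel_size = 65.35, z_step = NA_real_) {
  if (!is.numeric(pixels)) stop("`pixels` must be numeric", call. = FALSE)
  d <- dim(pixels)
  if (is.null(d)) stop("`pixels` must be a matrix or array", call. = FALSE)
  if (length(d) == 2L) dim(pixels) <- c(d, 1L, 1L)
  if (length(d) == 3L) dim(pixels) <- c(d[1:2], 1L, d[3])
  d <- dim(pixels)
  if (length(d) != 4L) stop("`pixels` must have 2 to 4 dimensions", call. = FALSE)
  if (length(channel_labels) != d[4]) {
    stop("`channel_labels` length (", length(channel_labels),
         ") does not match channel dimension (", d[4], ")", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) stop("duplicate channel labels", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || !is.finite(pixel_size) ||
      pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (nm/px)", call. = FALSE)
  }
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    stop("`pixels` must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(pixels = pixels, channel_labels = as.character(channel_labels),
         pixel_size = pixel_size, z_step = z_step),
    class = "img_stack"
  )
}

#' @export
print.img_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<img_stack> %d x %d px, %d z-plane(s), channels: %s; %.2f nm/px\n",
              d[2], d[1], d[3], paste(x$channel_labels, collapse = ", "),
              x$pixel_size))
  invisible(x)
}

n_z <- function(stack) dim(stack$pixels)[3]

channel_index <- function(stack, channel) {
  i <- match(channel, stack$channel_labels)
  if (is.na(i)) {
    stop("channel '", channel, "' not found; available: ",
         paste(stack$channel_labels, collapse = ", "), call. = FALSE)
  }
  i
}

#' Extract one channel plane
#'
#' @param stack An [image_stack()].
#' @param channel Channel label.
#' @param z Z-plane index (1-based); defaults to 1.
#' @return A numeric matrix `[y, x]`.
#' @export
get_channel <- function(stack, channel, z = 1L) {
  stack$pixels[, , z, channel_index(stack, channel)]
}

#' Maximum-intensity projection along z
#'
#' Collapses the defocus stack by the per-pixel maximum over z-planes, the
#' standard screening projection when foci may sit in different focal
#' planes. Identity for single-plane stacks.
#'
#' @inheritParams get_channel
#' @return A numeric matrix `[y, x]`.
#' @export
max_project <- function(stack, channel) {
  ci <- channel_index(stack, channel)
  planes <- stack$pixels[, , , ci, drop = FALSE]
  apply(planes, c(1, 2), max)
}

## --- internal numerics -----------------------------------------------------

# Normalized 2D Gaussian kernel, truncated at 5 sigma (odd size).
gauss_kernel <- function(sigma_px) {
  r <- max(1L, as.integer(ceiling(5 * sigma_px)))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma_px^2))
  k <- outer(g, g)
  k / sum(k)
}

# Zero-padded FFT convolution with an odd-sized kernel; output same size as m.
# Zero padding keeps photon counts conserved for patterns away from the border.
conv2_zero <- function(m, k) {
  dm <- dim(m); dk <- dim(k)
  n1 <- dm[1] + dk[1] - 1L; n2 <- dm[2] + dk[2] - 1L
  M <- matrix(0, n1, n2); M[seq_len(dm[1]), seq_len(dm[2])] <- m
  K <- matrix(0, n1, n2); K[seq_len(dk[1]), seq_len(dk[2])] <- k
  full <- Re(stats::fft(stats::fft(M) * stats::fft(K), inverse = TRUE)) / (n1 * n2)
  off <- (dk - 1L) %/% 2L
  out <- full[(1L + off[1]):(off[1] + dm[1]), (1L + off[2]):(off[2] + dm[2])]
  # FFT round-off can leave tiny negative values
  out[out < 0 & out > -1e-9] <- 0
  out
}

# Gaussian blur of a single plane (sigma in px).
blur2d <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  conv2_zero(m, gauss_kernel(sigma_px))
}

# Otsu threshold on arbitrary-scale values (scale-invariant by construction).
otsu_threshold <- function(values) {
  v <- values[is.finite(values)]
  rng <- range(v)
  if (diff(rng) <= 0) return(rng[1])
  img <- EBImage::Image(matrix((v - rng[1]) / diff(rng), nrow = 1))
  thr <- EBImage::otsu(img, range = c(0, 1), levels = 256)
  rng[1] + thr * diff(rng)
}

# Robust background/noise of the non-chromosome pixels inside a mask:
# pixels at or below the Otsu split are treated as cytoplasmic background.
mask_background <- function(image, mask) {
  v <- image[mask]
  thr <- otsu_threshold(v)
  low <- v[v <= thr]
  if (length(low) < 5L) low <- v
  list(bg = stats::median(low),
       noise = max(stats::mad(low), 1e-12),
       otsu = thr)
}

# 0-based pixel-center coordinate grids for a matrix [y, x].
coord_grids <- function(dm) {
  list(x = matrix(rep(seq_len(dm[2]) - 1, each = dm[1]), dm[1], dm[2]),
       y = matrix(rep(seq_len(dm[1]) - 1, times = dm[2]), dm[1], dm[2]))
}

## --- TIFF IO ---------------------------------------------------------------

#' Read a multichannel TIFF into an image stack
#'
#' Pages are interpreted z-fastest within channel: page
#' `(c - 1) * n_z + z` holds channel `c`, plane `z`. Files written by
#' [write_stack()] store integer camera counts as `count/65535` in 16-bit
#' samples; values are rescaled and re-rounded on read, so integer count
#' images round-trip exactly.
#'
#' @param path TIFF file path.
#' @param channel_map Named list/vector mapping channel labels to 1-based
#'   channel indices, e.g. `list(DNA = 1, ParB = 2)`.
#' @param pixel_size Pixel size in nm/px to attach (the file is not trusted
#'   for physical calibration).
#' @param n_z Number of z-planes per channel (default 1).
#' @param z_step Z spacing in nm (default `NA`).
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel_map, pixel_size = 65.35, n_z = 1L,
                       z_step = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n_pages <- length(pages)
  if (n_pages %% n_z != 0) {
    stop("page count (", n_pages, ") is not a multiple of n_z (", n_z,
         "): ambiguous z/channel axes", call. = FALSE)
  }
  n_ch_file <- n_pages %/% n_z
  idx <- unlist(channel_map)
  if (is.null(names(channel_map)) || any(names(channel_map) == "")) {
    stop("`channel_map` must be fully named", call. = FALSE)
  }
  bad <- idx[idx < 1 | idx > n_ch_file]
  if (length(bad)) {
    stop("channel_map index ", bad[1], " outside file channels 1..",
         n_ch_file, call. = FALSE)
  }
  dmy <- dim(pages[[1]])[1:2]
  px <- array(0, c(dmy[1], dmy[2], n_z, length(idx)))
  for (j in seq_along(idx)) {
    for (z in seq_len(n_z)) {
      pg <- pages[[(idx[j] - 1L) * n_z + z]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1]
      px[, , z, j] <- round(pg * 65535)
    }
  }
  image_stack(px, names(channel_map), pixel_size = pixel_size, z_step = z_step)
}

#' Write an image stack as a multipage 16-bit TIFF
#'
#' Values are stored as `count/65535` with 16 bits per sample; integer
#' counts in `[0, 65535]` (the camera ADU convention of the simulator)
#' round-trip exactly through [read_stack()].
#'
#' @param stack An [image_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$pixels)
  if (max(stack$pixels) > 65535) {
    stop("pixel values exceed 65535; 16-bit TIFF cannot store them", call. = FALSE)
  }
  pages <- vector("list", d[3] * d[4])
  i <- 0L
  for (ch in seq_len(d[4])) {
    for (z in seq_len(d[3])) {
      i <- i + 1L
      pages[[i]] <- stack$pixels[, , z, ch] / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}
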