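#' Parameters for the synthetic cell generator
#'
#' Defines one simulated expanded (spheroidal, wall-less) cell and its
#' fluorescence channels. The geometry emulates the unconfined chromosome
#' phenotypes seen in volume-expanded *B. subtilis*: a crescent arc with the
#' ParB/ori focus at one tip, a closed torus, a compact blob, or an
#' "other" (non-annular) pattern. Channels rendered: `DNA` (HbsU/dye
#' proxy), `ParB` (single psf-limited ori focus), `SMC` (DNA-coupled with
#' origin enrichment), `cell` (uniform membrane/phase proxy disc used for
#' segmentation), and optionally `ter` when `n_ter_foci > 0`.
#'
#' Lengths follow field conventions: pixel size and PSF/ribbon widths in
#' nm, cell/arc geometry in micrometers. All sizes default to the imaging
#' regime of expanded-cell microscopy: 65.35 nm/px pixels, cells of
#' diameter 2.3 um, crescent arcs spanning 90-180 degrees, an isotropic
#' Gaussian PSF of sigma 120 nm, and a 1.6-fold SMC enrichment at the
#' origin.
#'
#' @param pixel_size nm per pixel.
#' @param image_shape `c(ny, nx)` in pixels.
#' @param n_z Number of z-planes; planes away from focus are rendered with
#'   a defocus-inflated PSF.
#' @param z_step Z spacing in nm.
#' @param cell_diameter Cell (disc) diameter in um.
#' @param shape_class One of `"crescent"`, `"toroid"`, `"compact"`,
#'   `"other"`.
#' @param arc_radius Backbone arc radius in um.
#' @param arc_span Arc span in degrees; `NA` draws from \[90, 180\] for
#'   crescents. Toroids always use 360.
#' @param arc_phase_deg Angular position of the ori tip in degrees; `NA`
#'   draws uniformly.
#' @param arc_direction +1 (counterclockwise) or -1; `NA` draws randomly.
#' @param arc_width_sigma Transverse Gaussian width of the DNA ribbon (nm).
#' @param density_model `"uniform"`, `"exponential"` (decay from ori with
#'   length `density_decay_um`), or `"piecewise"` (constant on intervals).
#' @param density_decay_um Exponential decay length lambda in um.
#' @param density_breaks_um,density_weights For `"piecewise"`: interval
#'   breakpoints (starting at 0, ending at the arc length or beyond) and
#'   one non-negative relative weight per interval.
#' @param primary_cluster_fraction Fraction of DNA placed in an
#'   ori-proximal blob.
#' @param primary_cluster_sigma Blob width (nm), at least the PSF width.
#' @param secondary_cluster_fractions,secondary_cluster_positions_um
#'   Fractions and arc-length positions of secondary blobs.
#' @param secondary_cluster_sigma Width of secondary blobs (nm).
#' @param compact_sigma Width (nm) of the single blob for
#'   `shape_class = "compact"`.
#' @param other_rod_length_um Length of the straight-bar pattern used for
#'   `shape_class = "other"`.
#' @param n_parb_foci Number of ParB/ori-marker foci (the first sits at the
#'   ori; extras are placed randomly inside the cell, mutually separated).
#' @param parb_photons Photons per ParB focus.
#' @param smc_coupling SMC channel photon budget as a multiple of
#'   `photon_budget`.
#' @param smc_ori_enrichment Target fold-increase of the SMC profile at the
#'   origin relative to its own mean along the chromosome.
#' @param smc_enrichment_sigma_um Width of the origin enrichment bump (um).
#' @param n_ter_foci Number of ter-marker foci (0 disables the channel; the
#'   first sits at the ter tip).
#' @param ter_photons Photons per ter focus.
#' @param ter_diffuse_fraction Fraction of total ter-channel photons spread
#'   uniformly over the cell, emulating the low signal-to-noise of sparse
#'   ter labels.
#' @param psf_sigma Isotropic Gaussian PSF sigma (nm).
#' @param photon_budget Total DNA-channel photons per cell.
#' @param cell_fill_level Mean counts/px of the `cell` proxy disc.
#' @param background_level Camera background offset (counts/px).
#' @param read_noise_sigma Gaussian read noise sd (counts).
#' @param noise If `FALSE`, return the noiseless expected image (no Poisson
#'   or read noise, no integer rounding).
#' @param seed Integer seed making the cell fully reproducible; `NULL`
#'   uses the current RNG state.
#'
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(pixel_size = 65.35,
                       image_shape = c(64L, 64L),
                       n_z = 1L,
                       z_step = 200,
                       cell_diameter = 2.3,
                       shape_class = c("crescent", "toroid", "compact", "other"),
                       arc_radius = 0.75,
                       arc_span = NA_real_,
                       arc_phase_deg = NA_real_,
                       arc_direction = NA_real_,
                       arc_width_sigma = 150,
                       density_model = c("uniform", "exponential", "piecewise"),
                       density_decay_um = 1.0,
                       density_breaks_um = NULL,
                       density_weights = NULL,
                       primary_cluster_fraction = 0,
                       primary_cluster_sigma = 180,
                       secondary_cluster_fractions = numeric(0),
                       secondary_cluster_positions_um = numeric(0),
                       secondary_cluster_sigma = 180,
                       compact_sigma = 250,
                       other_rod_length_um = 1.9,
                       n_parb_foci = 1L,
                       parb_photons = 2e4,
                       smc_coupling = 1,
                       smc_ori_enrichment = 1.6,
                       smc_enrichment_sigma_um = 0.4,
                       n_ter_foci = 0L,
                       ter_photons = 5e3,
                       ter_diffuse_fraction = 0.4,
                       psf_sigma = 120,
                       photon_budget = 2e5,
                       cell_fill_level = 30,
                       background_level = 5,
                       read_noise_sigma = 2,
                       noise = TRUE,
                       seed = NULL) {
  shape_class <- match.arg(shape_class)
  density_model <- match.arg(density_model)
  p <- as.list(environment())

  chk_pos <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("sim_params: `", field, "` must be a single positive number",
           call. = FALSE)
    }
  }
  for (f in c("pixel_size", "cell_diameter", "arc_radius", "arc_width_sigma",
              "density_decay_um", "primary_cluster_sigma",
              "secondary_cluster_sigma", "compact_sigma", "other_rod_length_um",
              "parb_photons", "psf_sigma", "photon_budget", "cell_fill_level",
              "smc_enrichment_sigma_um", "ter_photons")) {
    chk_pos(f)
  }
  for (f in c("background_level", "read_noise_sigma", "smc_coupling")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("sim_params: `", f, "` must be a single non-negative number",
           call. = FALSE)
    }
  }
  if (length(p$image_shape) != 2L || any(p$image_shape < 16)) {
    stop("sim_params: `image_shape` must be two pixel counts >= 16", call. = FALSE)
  }
  p$image_shape <- as.integer(p$image_shape)
  if (p$n_z < 1) stop("sim_params: `n_z` must be >= 1", call. = FALSE)
  p$n_z <- as.integer(p$n_z)
  frac_in_01 <- function(field) {
    v <- p[[field]]
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
      stop("sim_params: `", field, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  frac_in_01("primary_cluster_fraction")
  frac_in_01("secondary_cluster_fractions")
  frac_in_01("ter_diffuse_fraction")
  tot <- p$primary_cluster_fraction + sum(p$secondary_cluster_fractions)
  if (tot > 1 + 1e-12) {
    stop("sim_params: `primary_cluster_fraction` + secondary fractions must be <= 1",
         call. = FALSE)
  }
  if (length(p$secondary_cluster_fractions) !=
      length(p$secondary_cluster_positions_um)) {
    stop("sim_params: `secondary_cluster_positions_um` must match ",
         "`secondary_cluster_fractions` in length", call. = FALSE)
  }
  if (!is.na(p$arc_span) && (p$arc_span <= 0 || p$arc_span > 360)) {
    stop("sim_params: `arc_span` must lie in (0, 360]", call. = FALSE)
  }
  if (shape_class == "toroid") p$arc_span <- 360
  if (!is.na(p$arc_direction) && !p$arc_direction %in% c(-1, 1)) {
    stop("sim_params: `arc_direction` must be +1 or -1", call. = FALSE)
  }
  if (p$density_model == "piecewise") {
    if (is.null(p$density_breaks_um) || is.null(p$density_weights) ||
        length(p$density_weights) != length(p$density_breaks_um) - 1L ||
        any(p$density_weights < 0) || is.unsorted(p$density_breaks_um)) {
      stop("sim_params: piecewise density needs sorted `density_breaks_um` and ",
           "one non-negative `density_weights` entry per interval", call. = FALSE)
    }
  }
  if (p$arc_radius * 2 > p$cell_diameter) {
    stop("sim_params: `arc_radius` must fit inside the cell (2*arc_radius <= cell_diameter)",
         call. = FALSE)
  }
  structure(p, class = "sim_params")
}

## --- low-level rendering ---------------------------------------------------

# Bilinear deposition of weighted points at 0-based sub-pixel positions.
splat_points <- function(dm, x, y, w) {
  if (length(w) == 1L) w <- rep(w, length(x))
  v <- numeric(prod(dm))
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  for (dx in 0:1) {
    for (dy in 0:1) {
      wx <- if (dx == 0) 1 - fx else fx
      wy <- if (dy == 0) 1 - fy else fy
      cx <- x0 + dx; cy <- y0 + dy
      ok <- cx >= 0 & cx < dm[2] & cy >= 0 & cy < dm[1]
      if (any(ok)) {
        li <- cx[ok] * dm[1] + cy[ok] + 1  # column-major linear index
        agg <- rowsum(w[ok] * wx[ok] * wy[ok], group = li)
        at <- as.integer(rownames(agg))
        v[at] <- v[at] + agg[, 1]
      }
    }
  }
  matrix(v, dm[1], dm[2])
}

# Pixel-integrated Gaussian emitter: expected counts in each pixel are the
# product of error-function integrals over the pixel footprint, so a spot
# rendered at any sub-pixel position sums to exactly one photon (within
# the frame) and matches the camera model used by the spot fitter.
gauss_pixel_spot <- function(dm, x0, y0, sigma_px) {
  xs <- seq_len(dm[2]) - 1
  ys <- seq_len(dm[1]) - 1
  fx <- stats::pnorm(xs + 0.5, x0, sigma_px) - stats::pnorm(xs - 0.5, x0, sigma_px)
  fy <- stats::pnorm(ys + 0.5, y0, sigma_px) - stats::pnorm(ys - 0.5, y0, sigma_px)
  outer(fy, fx)
}

#' Render psf-limited spots onto a pixel grid
#'
#' Deposits point emitters at sub-pixel positions as pixel-integrated
#' Gaussians of width `sqrt(psf^2 + source^2)` (optionally widened by an
#' intrinsic source size). Total photons are conserved for spots away
#' from the border.
#'
#' @param image_shape `c(ny, nx)` pixels.
#' @param x_px,y_px 0-based sub-pixel positions.
#' @param photons Photons per spot.
#' @param psf_sigma_px PSF sigma in pixels.
#' @param source_sigma_px Intrinsic source width in pixels (default 0).
#' @return Numeric matrix of expected photon counts.
#' @export
render_spots <- function(image_shape, x_px, y_px, photons, psf_sigma_px,
                         source_sigma_px = 0) {
  stopifnot(length(x_px) == length(y_px), length(photons) %in% c(1L, length(x_px)))
  if (length(photons) == 1L) photons <- rep(photons, length(x_px))
  sigma <- sqrt(psf_sigma_px^2 + source_sigma_px^2)
  m <- matrix(0, image_shape[1], image_shape[2])
  for (i in seq_along(x_px)) {
    m <- m + photons[i] * gauss_pixel_spot(image_shape, x_px[i], y_px[i], sigma)
  }
  m
}

# Linear density values (unnormalized) on an arc-length grid.
density_on_grid <- function(p, s_um) {
  switch(p$density_model,
    uniform = rep(1, length(s_um)),
    exponential = exp(-s_um / p$density_decay_um),
    piecewise = {
      iv <- findInterval(s_um, p$density_breaks_um, rightmost.closed = TRUE)
      w <- c(0, p$density_weights, 0)  # outside the break range: zero
      w[iv + 1L]
    })
}

defocus_sigma_px <- function(psf_sigma_px, dz_nm, pixel_size) {
  # simple widefield defocus model: PSF width grows with |dz|
  sqrt(psf_sigma_px^2 + (0.5 * dz_nm / pixel_size)^2)
}

## --- simulate_cell ---------------------------------------------------------

#' Simulate one expanded cell with ground truth
#'
#' Renders each channel as (ideal pattern) convolved with a Gaussian PSF
#' plus a camera background, then applies Poisson shot noise and Gaussian
#' read noise and rounds to integer camera counts. Returns both the image
#' stack and a `sim_truth` object recording the geometry, the normalized
#' linear DNA density sampled along the backbone, the cluster table, and
#' per-channel noiseless totals, so recovery can be scored exactly.
#'
#' @param params A [sim_params()] object.
#' @return A list with elements `stack` ([image_stack()]) and `truth`
#'   (class `sim_truth`).
#' @export
simulate_cell <- function(params) {
  if (!inherits(params, "sim_params")) {
    stop("`params` must come from sim_params()", call. = FALSE)
  }
  if (!is.null(params$seed)) {
    return(withr::with_seed(params$seed, simulate_cell_impl(params)))
  }
  simulate_cell_impl(params)
}

simulate_cell_impl <- function(p) {
  px <- p$pixel_size
  dm <- p$image_shape
  center <- c((dm[2] - 1) / 2, (dm[1] - 1) / 2)  # (x, y), 0-based
  psf_px <- p$psf_sigma / px
  ribbon_px <- p$arc_width_sigma / px
  cell_r_px <- p$cell_diameter * 1000 / px / 2

  # resolve random geometry
  span <- p$arc_span
  if (is.na(span)) {
    span <- if (p$shape_class == "crescent") stats::runif(1, 90, 180) else 180
  }
  phase <- if (is.na(p$arc_phase_deg)) stats::runif(1, 0, 360) else p$arc_phase_deg
  dir <- if (is.na(p$arc_direction)) sample(c(-1, 1), 1) else p$arc_direction

  R_px <- p$arc_radius * 1000 / px
  theta0 <- phase * pi / 180

  # --- backbone sampling grid (arc length s, positions) --------------------
  if (p$shape_class %in% c("crescent", "toroid")) {
    L_um <- (span * pi / 180) * p$arc_radius
    ds_um <- px / 4 / 1000
    s_um <- seq(0, L_um, by = ds_um)
    theta <- theta0 + dir * (s_um / p$arc_radius)
    gx <- center[1] + R_px * cos(theta)
    gy <- center[2] + R_px * sin(theta)
    ori <- c(gx[1], gy[1])
    ter <- c(gx[length(gx)], gy[length(gy)])
    arc_like <- TRUE
  } else if (p$shape_class == "compact") {
    L_um <- 0
    s_um <- 0
    gx <- center[1]; gy <- center[2]
    ori <- ter <- center
    arc_like <- FALSE
  } else { # other: straight bar through the cell center
    L_um <- p$other_rod_length_um
    ds_um <- px / 4 / 1000
    s_um <- seq(0, L_um, by = ds_um)
    L_px <- L_um * 1000 / px
    ux <- cos(theta0); uy <- sin(theta0)
    gx <- center[1] + (s_um * 1000 / px - L_px / 2) * ux
    gy <- center[2] + (s_um * 1000 / px - L_px / 2) * uy
    ori <- c(gx[1], gy[1])
    ter <- c(gx[length(gx)], gy[length(gy)])
    arc_like <- FALSE
  }

  # --- DNA mass distribution ------------------------------------------------
  smooth_frac <- 1 - p$primary_cluster_fraction - sum(p$secondary_cluster_fractions)
  rho <- density_on_grid(p, s_um)
  if (sum(rho) <= 0) stop("density model assigns zero mass to the arc", call. = FALSE)
  rho <- rho / sum(rho)

  clusters <- NULL
  if (p$shape_class == "compact") {
    clusters <- tibble::tibble(s_um = 0, x_px = center[1], y_px = center[2],
                               fraction = 1, sigma_nm = p$compact_sigma,
                               primary = TRUE)
    smooth_frac <- 0
  } else {
    if (p$primary_cluster_fraction > 0) {
      clusters <- tibble::tibble(s_um = 0, x_px = ori[1], y_px = ori[2],
                                 fraction = p$primary_cluster_fraction,
                                 sigma_nm = p$primary_cluster_sigma,
                                 primary = TRUE)
    }
    if (length(p$secondary_cluster_fractions)) {
      s_sec <- pmin(p$secondary_cluster_positions_um, L_um)
      i_sec <- vapply(s_sec, function(s) which.min(abs(s_um - s)), integer(1))
      clusters <- dplyr::bind_rows(clusters, tibble::tibble(
        s_um = s_um[i_sec], x_px = gx[i_sec], y_px = gy[i_sec],
        fraction = p$secondary_cluster_fractions,
        sigma_nm = p$secondary_cluster_sigma, primary = FALSE))
    }
  }

  # truth linear density: smooth part + cluster mass at its grid point
  dens <- rho * smooth_frac
  if (!is.null(clusters)) {
    for (i in seq_len(nrow(clusters))) {
      j <- which.min(abs(s_um - clusters$s_um[i]))
      dens[j] <- dens[j] + clusters$fraction[i]
    }
  }

  # --- render DNA channel ---------------------------------------------------
  render_mass <- function(weights, extra_sigma_px) {
    m <- splat_points(dm, gx, gy, weights)
    blur2d(m, sqrt(extra_sigma_px^2 + psf_px^2))
  }
  dna <- matrix(0, dm[1], dm[2])
  if (smooth_frac > 0) {
    dna <- dna + p$photon_budget * render_mass(rho * smooth_frac, ribbon_px)
  }
  if (!is.null(clusters)) {
    dna <- dna + render_spots(dm, clusters$x_px, clusters$y_px,
                              p$photon_budget * clusters$fraction,
                              psf_px, clusters$sigma_nm / px)
  }

  # --- SMC channel: DNA-coupled with an ori-proximal enrichment bump -------
  bump <- exp(-s_um^2 / (2 * p$smc_enrichment_sigma_um^2))
  if (arc_like) {
    m_rho <- mean(dens); m_rho_b <- mean(dens * bump); rho0 <- dens[1]
    denom <- rho0 - p$smc_ori_enrichment * m_rho_b
    E <- if (denom > 1e-12) {
      p$smc_ori_enrichment * (m_rho - m_rho_b) / denom
    } else p$smc_ori_enrichment
    E <- max(E, 0)
  } else {
    E <- 1
  }
  enr <- 1 + (E - 1) * bump
  smc_w_smooth <- rho * smooth_frac * enr
  smc <- matrix(0, dm[1], dm[2])
  smc_cluster_w <- numeric(0)
  if (!is.null(clusters)) {
    smc_cluster_w <- clusters$fraction *
      (1 + (E - 1) * exp(-clusters$s_um^2 / (2 * p$smc_enrichment_sigma_um^2)))
  }
  smc_total_w <- sum(smc_w_smooth) + sum(smc_cluster_w)
  smc_budget <- p$photon_budget * p$smc_coupling
  if (smc_total_w > 0) {
    if (sum(smc_w_smooth) > 0) {
      smc <- smc + smc_budget * render_mass(smc_w_smooth / smc_total_w, ribbon_px)
    }
    if (length(smc_cluster_w) && sum(smc_cluster_w) > 0) {
      smc <- smc + render_spots(dm, clusters$x_px, clusters$y_px,
                                smc_budget * smc_cluster_w / smc_total_w,
                                psf_px, clusters$sigma_nm / px)
    }
  }

  # --- ParB channel ---------------------------------------------------------
  parb_pos <- matrix(c(ori[1], ori[2]), ncol = 2)
  if (p$n_parb_foci > 1L) {
    extra <- place_random_in_disc(p$n_parb_foci - 1L, center, cell_r_px * 0.8,
                                  min_sep_px = 3 * psf_px,
                                  avoid = parb_pos, max_tries = 500)
    parb_pos <- rbind(parb_pos, extra)
  }
  parb <- render_spots(dm, parb_pos[, 1], parb_pos[, 2], p$parb_photons, psf_px)

  # --- cell proxy channel ---------------------------------------------------
  grids <- coord_grids(dm)
  in_cell <- (grids$x - center[1])^2 + (grids$y - center[2])^2 <= cell_r_px^2
  cellch <- blur2d(p$cell_fill_level * in_cell, psf_px)

  channels <- list(DNA = dna, ParB = parb, SMC = smc, cell = cellch)

  # --- optional ter channel --------------------------------------------------
  ter_pos <- NULL
  if (p$n_ter_foci > 0L) {
    ter_pos <- matrix(c(ter[1], ter[2]), ncol = 2)
    if (p$n_ter_foci > 1L) {
      extra <- place_random_in_disc(p$n_ter_foci - 1L, center, cell_r_px * 0.8,
                                    min_sep_px = 3 * psf_px,
                                    avoid = ter_pos, max_tries = 500)
      ter_pos <- rbind(ter_pos, extra)
    }
    spot_budget <- p$ter_photons * (1 - p$ter_diffuse_fraction)
    terch <- render_spots(dm, ter_pos[, 1], ter_pos[, 2], spot_budget, psf_px)
    diffuse_total <- p$ter_photons * p$n_ter_foci * p$ter_diffuse_fraction
    terch <- terch + blur2d(diffuse_total * in_cell / sum(in_cell), psf_px)
    channels$ter <- terch
  }

  ideal_totals <- vapply(channels, sum, numeric(1))

  # --- z-stack, background, noise -------------------------------------------
  n_ch <- length(channels)
  arr <- array(0, c(dm[1], dm[2], p$n_z, n_ch))
  z_center <- (p$n_z + 1) / 2
  for (ci in seq_len(n_ch)) {
    base <- channels[[ci]]
    for (z in seq_len(p$n_z)) {
      dz <- (z - z_center) * p$z_step
      plane <- if (p$n_z == 1L || abs(dz) < 1e-9) {
        base
      } else {
        extra <- sqrt(defocus_sigma_px(psf_px, dz, px)^2 - psf_px^2)
        blur2d(base, extra)
      }
      arr[, , z, ci] <- plane + p$background_level
    }
  }
  if (p$noise) {
    nn <- length(arr)
    noisy <- stats::rpois(nn, lambda = as.vector(arr)) +
      stats::rnorm(nn, 0, p$read_noise_sigma)
    arr <- array(pmin(pmax(round(noisy), 0), 65535), dim = dim(arr))
  }

  stack <- image_stack(arr, names(channels), pixel_size = px,
                       z_step = if (p$n_z > 1L) p$z_step else NA_real_)

  truth <- structure(list(
    shape_label = p$shape_class,
    ori_xy_px = ori, ter_xy_px = ter,
    ori_xy_nm = ori * px, ter_xy_nm = ter * px,
    center_xy_px = center,
    arc_radius_px = if (arc_like) R_px else NA_real_,
    arc_radius_nm = if (arc_like) R_px * px else NA_real_,
    arc_span_deg = if (arc_like) span else NA_real_,
    arc_direction = if (arc_like) dir else NA_real_,
    arc_phase_deg = if (arc_like) phase else NA_real_,
    arc_length_um = L_um,
    density = tibble::tibble(s_um = s_um, x_px = gx, y_px = gy,
                             density = dens / sum(dens)),
    clusters = if (is.null(clusters)) {
      tibble::tibble(s_um = numeric(0), x_px = numeric(0), y_px = numeric(0),
                     fraction = numeric(0), sigma_nm = numeric(0),
                     primary = logical(0))
    } else clusters,
    cell_radius_px = cell_r_px,
    parb_positions_px = parb_pos,
    ter_positions_px = ter_pos,
    channel_totals = ideal_totals,
    smc_bump_amplitude = E,
    pixel_size = px,
    params = p
  ), class = "sim_truth")

  list(stack = stack, truth = truth)
}

# Rejection sampling of points in a disc with minimum mutual separation.
place_random_in_disc <- function(n, center, radius_px, min_sep_px, avoid = NULL,
                                 max_tries = 500) {
  pts <- if (is.null(avoid)) matrix(numeric(0), ncol = 2) else avoid
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      r <- radius_px * sqrt(stats::runif(1))
      a <- stats::runif(1, 0, 2 * pi)
      cand <- c(center[1] + r * cos(a), center[2] + r * sin(a))
      if (nrow(pts) == 0 ||
          min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >= min_sep_px) {
        pts <- rbind(pts, cand)
        out <- rbind(out, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place point with required separation", call. = FALSE)
  }
  out
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %s; ori at (%.1f, %.1f) px; arc %.0f deg, L = %.2f um\n",
              x$shape_label, x$ori_xy_px[1], x$ori_xy_px[2],
              ifelse(is.na(x$arc_span_deg), 0, x$arc_span_deg), x$arc_length_um))
  invisible(x)
}

## --- simulate_condition ----------------------------------------------------

#' Simulate a population of cells for one condition
#'
#' Renders `n_cells` independent cells with per-cell seeds derived
#' reproducibly from the master seed, plus a manifest recording every
#' cell's parameters. `params` may be a single [sim_params()] (replicated)
#' or a list of them (cycled in order), or a shape mixture can be requested
#' via `shape_mix`.
#'
#' @param params A [sim_params()] object or list of them.
#' @param n_cells Number of cells (>= 1).
#' @param seed Master seed; per-cell seeds are drawn from it.
#' @param shape_mix Optional named fractions over shape classes, e.g.
#'   `c(crescent = 0.5, toroid = 0.5)`; class counts are allocated
#'   deterministically by largest remainder.
#' @return A list with `cells` (list of `list(stack, truth)`) and
#'   `manifest` (tibble: cell_id, seed, shape_class, arc geometry).
#' @export
simulate_condition <- function(params, n_cells, seed = 1L, shape_mix = NULL) {
  if (n_cells < 1) stop("`n_cells` must be >= 1", call. = FALSE)
  single <- inherits(params, "sim_params")
  if (!single && !all(vapply(params, inherits, logical(1), "sim_params"))) {
    stop("`params` must be a sim_params object or a list of them", call. = FALSE)
  }
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n_cells))

  classes <- NULL
  if (!is.null(shape_mix)) {
    if (!single) stop("`shape_mix` requires a single `params` object", call. = FALSE)
    fr <- shape_mix / sum(shape_mix)
    counts <- floor(fr * n_cells)
    rem <- n_cells - sum(counts)
    if (rem > 0) {
      extra <- order(fr * n_cells - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1L
    }
    classes <- rep(names(fr), counts)
  }

  cells <- vector("list", n_cells)
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    p_i <- if (single) params else params[[(i - 1L) %% length(params) + 1L]]
    p_i$seed <- seeds[i]
    if (!is.null(classes)) p_i$shape_class <- classes[i]
    p_i <- do.call(sim_params, unclass(p_i))
    cells[[i]] <- simulate_cell(p_i)
    tr <- cells[[i]]$truth
    rows[[i]] <- tibble::tibble(
      cell_id = i, seed = seeds[i], shape_class = tr$shape_label,
      arc_span_deg = tr$arc_span_deg, arc_radius_um = tr$arc_radius_nm / 1000,
      arc_length_um = tr$arc_length_um,
      photon_budget = p_i$photon_budget, psf_sigma_nm = p_i$psf_sigma,
      pixel_size = p_i$pixel_size)
  }
  list(cells = cells, manifest = dplyr::bind_rows(rows))
}

#' Composite single-cell stacks onto one field of view
#'
#' Places cell tiles on a regular grid with a guaranteed gap, erroring if
#' the requested field cannot hold them without overlap.
#'
#' @param cells List of `list(stack, truth)` as from [simulate_condition()].
#' @param fov_shape `c(ny, nx)` of the field; default packs tightly.
#' @param gap_px Gap between tiles in pixels.
#' @return A list with `stack` (the composited [image_stack()]) and
#'   `offsets` (tibble of each cell's (x, y) pixel offset in the field).
#' @export
composite_field <- function(cells, fov_shape = NULL, gap_px = 4L) {
  n <- length(cells)
  dm <- dim(cells[[1]]$stack$pixels)
  tile <- dm[1:2] + gap_px
  ncol_grid <- ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  need <- c(nrow_grid * tile[1] + gap_px, ncol_grid * tile[2] + gap_px)
  if (is.null(fov_shape)) fov_shape <- need
  if (any(fov_shape < need)) {
    stop("cannot place ", n, " cells in a ", fov_shape[1], "x", fov_shape[2],
         " field without overlap (need ", need[1], "x", need[2], ")",
         call. = FALSE)
  }
  arr <- array(0, c(fov_shape[1], fov_shape[2], dm[3], dm[4]))
  offs <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    gr <- (i - 1L) %/% ncol_grid
    gc <- (i - 1L) %% ncol_grid
    oy <- gap_px + gr * tile[1]
    ox <- gap_px + gc * tile[2]
    arr[oy + seq_len(dm[1]), ox + seq_len(dm[2]), , ] <- cells[[i]]$stack$pixels
    offs[i, ] <- c(ox, oy)
  }
  s1 <- cells[[1]]$stack
  list(stack = image_stack(arr, s1$channel_labels, s1$pixel_size, s1$z_step),
       offsets = tibble::tibble(cell_id = seq_len(n),
                                offset_x_px = offs[, 1], offset_y_px = offs[, 2]))
}

#' Integrate true DNA density within a radius of a point
#'
#' Sums the ground-truth linear density (including cluster mass) at arc
#' grid points whose Euclidean distance to `origin_xy_px` is at most
#' `radius_nm`.
#'
#' @param truth A `sim_truth` object.
#' @param radius_nm Radius in nm (default 500).
#' @param origin_xy_px Reference point, default the true ori.
#' @return Fraction of total DNA mass in \[0, 1\].
#' @export
truth_fraction_within_radius <- function(truth, radius_nm = 500,
                                         origin_xy_px = truth$ori_xy_px) {
  d_nm <- sqrt((truth$density$x_px - origin_xy_px[1])^2 +
               (truth$density$y_px - origin_xy_px[2])^2) * truth$pixel_size
  sum(truth$density$density[d_nm <= radius_nm])
}
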