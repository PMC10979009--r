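psf_px <- 120 / 65.35

spotset_at <- function(x, y, intensity = rep(1, length(x)), px = 65.35) {
  tbl <- tibble::tibble(spot_id = seq_along(x), x_px = x, y_px = y,
                        amplitude = intensity, sigma_px = psf_px,
                        intensity = intensity)
  attr(tbl, "total_cell_signal") <- sum(intensity)
  attr(tbl, "pixel_size") <- px
  class(tbl) <- c("spot_set", class(tbl))
  tbl
}

test_that("a single rendered spot decomposes into one full-intensity spot", {
  img <- render_spots(c(40, 40), 21.3, 18.7, 1e4, psf_px)
  sp <- decompose_spots(img, matrix(TRUE, 40, 40))
  expect_equal(nrow(sp), 1L)
  expect_lt(abs(sp$x_px - 21.3), 0.2)
  expect_lt(abs(sp$y_px - 18.7), 0.2)
  frac <- sum(sp$intensity) / attr(sp, "total_cell_signal")
  expect_equal(frac, 1, tolerance = 0.02)
})

test_that("two equal spots three sigma apart recover equal fractions", {
  img <- render_spots(c(40, 40), c(14, 14 + 3 * psf_px), c(20, 20),
                      1e4, psf_px)
  sp <- decompose_spots(img, matrix(TRUE, 40, 40))
  cl <- group_clusters(sp, link_radius_nm = 65.35)  # tight: one per spot
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$relative_intensity, c(0.5, 0.5), tolerance = 0.05)
})

test_that("blank images produce no spots with a below-noise stop", {
  sp <- decompose_spots(matrix(0, 30, 30), matrix(TRUE, 30, 30))
  expect_identical(nrow(sp), 0L)
  expect_identical(attr(sp, "stopping_reason"), "below_noise")
})

test_that("residual norms never increase during decomposition", {
  cc <- simulate_cell(sim_params(seed = 51, primary_cluster_fraction = 0.3))
  a <- analyze_cell(cc)
  sp <- decompose_spots(a$dna, a$mask)
  expect_true(all(diff(attr(sp, "residual_norm")) <= 1e-9))
})

test_that("psf linkage is transitive and gaps split clusters", {
  r <- 2.355 * 120  # FWHM link radius, nm
  px <- 65.35
  # chain A-B-C at 0.9 r spacing: one cluster despite |AC| = 1.8 r
  chain <- spotset_at(c(0, 0.9 * r / px, 1.8 * r / px), c(0, 0, 0))
  cl <- group_clusters(chain, psf_sigma_nm = 120)
  expect_equal(nrow(cl), 1L)
  expect_identical(sort(cl$spot_ids[[1]]), 1:3)
  oracle <- uf_single_linkage(cbind(chain$x_px, chain$y_px) * px, r)
  expect_true(same_partition(oracle, rep(1L, 3)))

  # two spots at 1.5 r: distinguishable gap, two clusters
  apart <- spotset_at(c(0, 1.5 * r / px), c(0, 0))
  expect_equal(nrow(group_clusters(apart, psf_sigma_nm = 120)), 2L)

  # single spot: one cluster containing it
  single <- spotset_at(5, 5)
  cl1 <- group_clusters(single)
  expect_equal(nrow(cl1), 1L)
  expect_true(cl1$is_primary)
})

test_that("linkage partitions match the union-find oracle on random spot sets", {
  set.seed(61)
  for (rep in 1:40) {
    n <- sample(1:12, 1)
    px <- 65.35
    pos <- matrix(stats::runif(2 * n, 0, 30), ncol = 2)
    radius <- stats::runif(1, 50, 600)
    sp <- spotset_at(pos[, 1], pos[, 2],
                     intensity = stats::runif(n, 0.5, 2))
    got <- group_clusters(sp, link_radius_nm = radius)
    memb_got <- integer(n)
    for (k in seq_len(nrow(got))) memb_got[got$spot_ids[[k]]] <- k
    memb_oracle <- uf_single_linkage(pos * px, radius)
    expect_true(same_partition(memb_got, memb_oracle))
  }
})

test_that("growing the linkage radius never increases the cluster count", {
  set.seed(62)
  pos <- matrix(stats::runif(20, 0, 25), ncol = 2)
  sp <- spotset_at(pos[, 1], pos[, 2])
  radii <- c(50, 150, 300, 600, 1200)
  counts <- vapply(radii, function(r)
    nrow(group_clusters(sp, link_radius_nm = r)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("cluster intensities account for the whole modeled signal", {
  img <- render_spots(c(48, 48), c(15, 32), c(20, 28), c(8e3, 4e3), psf_px)
  sp <- decompose_spots(img, matrix(TRUE, 48, 48))
  cl <- group_clusters(sp)
  expect_lte(sum(cl$relative_intensity), 1 + 1e-3)
  expect_equal(sum(cl$relative_intensity), 1, tolerance = 0.05)
  expect_identical(sum(cl$is_primary), 1L)
})

test_that("primary ranking prefers intensity with ParB proximity as tie-break", {
  sp <- spotset_at(c(0, 10, 20), c(0, 0, 0), intensity = c(0.4, 0.3, 0.3))
  cl <- group_clusters(sp, link_radius_nm = 100)
  expect_equal(cl$relative_intensity[cl$is_primary], 0.4)

  tied <- spotset_at(c(0, 20), c(0, 0), intensity = c(0.5, 0.5))
  near_right <- group_clusters(tied, link_radius_nm = 100,
                               parb_focus = list(x_px = 20, y_px = 0))
  expect_equal(near_right$centroid_x_px[near_right$is_primary], 20)
})

test_that("cluster-to-ori distances are exact on constructed geometry", {
  sp <- spotset_at(c(10, 20), c(10, 10), intensity = c(0.6, 0.4))
  cl <- group_clusters(sp, link_radius_nm = 100)
  st <- primary_cluster_stats(cl, list(x_px = 10, y_px = 10))
  expect_equal(st$distance_to_ori_nm[st$is_primary], 0)
  expect_equal(st$distance_to_ori_nm[!st$is_primary], 10 * 65.35)
  empty <- group_clusters(spotset_at(numeric(0), numeric(0)))
  expect_identical(nrow(primary_cluster_stats(empty, list(x_px = 0, y_px = 0))), 0L)
})

test_that("fraction_within_radius has the right limits and monotonicity", {
  img <- render_spots(c(40, 40), 20, 20, 1e4, psf_px)
  mask <- matrix(TRUE, 40, 40)
  expect_equal(fraction_within_radius(img, mask, c(20, 20), 500), 1,
               tolerance = 0.02)
  big <- fraction_within_radius(img, mask, c(20, 20),
                                radius_nm = 80 * 65.35)
  expect_equal(big, 1, tolerance = 1e-6)
  radii <- c(100, 200, 400, 800, 1600)
  cc <- simulate_cell(sim_params(seed = 63, primary_cluster_fraction = 0.4))
  a <- analyze_cell(cc)
  fr <- vapply(radii, function(r)
    fraction_within_radius(a$dna, a$mask, cc$truth$ori_xy_px, r), numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("uniform-arc origin fractions match the quadrature oracle", {
  span <- 160
  cc <- simulate_cell(sim_params(seed = 64, arc_span = span, noise = FALSE,
                                 background_level = 1e-9, arc_phase_deg = 10,
                                 arc_direction = 1))
  a <- analyze_cell(cc)
  oracle <- arc_fraction_oracle(0.75, span, 500)
  got <- fraction_within_radius(a$dna, a$mask, cc$truth$ori_xy_px, 500)
  # image-side estimate is blurred by the PSF; oracle is the exact density
  expect_lt(abs(got - oracle), 0.03)
  expect_lt(abs(truth_fraction_within_radius(cc$truth, 500) - oracle), 0.01)
})
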