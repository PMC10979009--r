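noiseless_cell <- function(seed, span = 150, phase = 30, dir = 1, ...) {
  simulate_cell(sim_params(seed = seed, noise = FALSE, background_level = 1e-9,
                           arc_span = span, arc_phase_deg = phase,
                           arc_direction = dir, ...))
}

test_that("the fitted annulus recovers center, radius and ori angle of a noiseless arc", {
  cc <- noiseless_cell(31)
  a <- analyze_cell(cc)
  bb <- fit_backbone(a$dna, a$mask, a$parb)
  expect_lt(abs(bb$center_x_px - cc$truth$center_xy_px[1]), 0.5)
  expect_lt(abs(bb$center_y_px - cc$truth$center_xy_px[2]), 0.5)
  expect_lt(abs(bb$radius_mean_px - cc$truth$arc_radius_px), 0.5)
  # ori angle within one angular bin (5 deg) of the truth phase
  truth_angle <- cc$truth$arc_phase_deg * pi / 180
  d <- abs(atan2(sin(bb$ori_angle - truth_angle), cos(bb$ori_angle - truth_angle)))
  expect_lt(d, 5 * pi / 180)
})

test_that("a full torus has complete angular support", {
  cc <- simulate_cell(sim_params(seed = 32, shape_class = "toroid",
                                 noise = FALSE, background_level = 1e-9,
                                 arc_phase_deg = 0, arc_direction = 1))
  a <- analyze_cell(cc)
  bb <- fit_backbone(a$dna, a$mask, a$parb)
  expect_equal(bb$angular_coverage_deg, 360)
})

test_that("uniform tori profile flat and profiles carry unit mean fold-increase", {
  cc <- simulate_cell(sim_params(seed = 33, shape_class = "toroid"))
  a <- analyze_cell(cc)
  bb <- fit_backbone(a$dna, a$mask, a$parb)
  prof <- align_and_flip(profile_along_backbone(cc$stack, bb))
  dna <- prof[prof$channel == "DNA" & !is.na(prof$fold_increase), ]
  obs <- dna[dna$s_um <= 0.9 * pi * cc$truth$arc_radius_nm / 1000, ]
  expect_true(all(abs(obs$fold_increase - 1) < 0.25))
  expect_lt(stats::sd(obs$fold_increase) / mean(obs$fold_increase), 0.1)
  for (ch in unique(prof$channel)) {
    expect_equal(mean(prof$fold_increase[prof$channel == ch], na.rm = TRUE), 1,
                 tolerance = 1e-6)
  }
})

test_that("noiseless uniform crescents give a near-flat interior profile", {
  cc <- noiseless_cell(34, span = 170)
  a <- analyze_cell(cc)
  prof <- align_and_flip(profile_along_backbone(
    cc$stack, fit_backbone(a$dna, a$mask, a$parb)))
  dna <- prof[prof$channel == "DNA" & !is.na(prof$fold_increase), ]
  L <- cc$truth$arc_length_um
  interior <- dna[dna$s_um > 0.4 & dna$s_um < L - 0.4, ]
  expect_lt(stats::sd(interior$raw_per_um) / mean(interior$raw_per_um), 0.02)
})

test_that("the ParB profile peaks in the first bins at the ori anchor", {
  cc <- simulate_cell(sim_params(seed = 35, arc_span = 150))
  a <- analyze_cell(cc)
  prof <- align_and_flip(profile_along_backbone(
    cc$stack, fit_backbone(a$dna, a$mask, a$parb)))
  parb <- prof[prof$channel == "ParB" & !is.na(prof$fold_increase), ]
  expect_lte(which.max(parb$fold_increase), 2)
})

test_that("per-cell decay lengths recover an exponential density model", {
  cc <- simulate_cell(sim_params(seed = 36, density_model = "exponential",
                                 density_decay_um = 1.0, arc_span = 170))
  a <- analyze_cell(cc)
  prof <- align_and_flip(profile_along_backbone(
    cc$stack, fit_backbone(a$dna, a$mask, a$parb)))
  lam <- estimate_decay_length(prof)
  expect_lt(abs(lam - 1.0), 0.15)
})

test_that("clockwise and counterclockwise crescents flip onto the same profile", {
  prof_of <- function(dir) {
    cc <- noiseless_cell(37, span = 140, phase = 20, dir = dir,
                         density_model = "exponential", density_decay_um = 1)
    a <- analyze_cell(cc)
    align_and_flip(profile_along_backbone(
      cc$stack, fit_backbone(a$dna, a$mask, a$parb)))
  }
  p1 <- prof_of(1)
  p2 <- prof_of(-1)
  # mirrored geometry reverses the handedness but not the physical profile
  expect_equal(p1$fold_increase, p2$fold_increase, tolerance = 0.05)
  expect_identical(attr(p1, "orientation_sign") * attr(p2, "orientation_sign"),
                   -1)
})

test_that("align_and_flip is involution-safe", {
  cc <- noiseless_cell(38)
  a <- analyze_cell(cc)
  prof <- profile_along_backbone(cc$stack, fit_backbone(a$dna, a$mask, a$parb))
  once <- align_and_flip(prof)
  twice <- align_and_flip(once)
  expect_identical(once, twice)
})

test_that("profiles are invariant to 90-degree image rotation", {
  cc <- noiseless_cell(39, span = 150, phase = 20)
  rot90 <- function(m) t(m)[, nrow(m):1]
  prof_of <- function(pix) {
    st <- image_stack(pix, cc$stack$channel_labels)
    a <- analyze_cell(list(stack = st, truth = cc$truth))
    align_and_flip(profile_along_backbone(
      st, fit_backbone(a$dna, a$mask, a$parb)))
  }
  arr1 <- cc$stack$pixels
  arr2 <- array(0, c(dim(arr1)[2], dim(arr1)[1], 1, dim(arr1)[4]))
  for (ch in seq_len(dim(arr1)[4])) arr2[, , 1, ch] <- rot90(arr1[, , 1, ch])
  p1 <- prof_of(arr1)
  p2 <- prof_of(arr2)
  expect_equal(p1$raw_per_um, p2$raw_per_um, tolerance = 1e-6)
})

test_that("compact blobs are rejected as not arc-like", {
  cc <- simulate_cell(sim_params(seed = 40, shape_class = "compact"))
  a <- analyze_cell(cc)
  expect_error(fit_backbone(a$dna, a$mask, a$parb),
               class = "shape_not_arclike")
})

test_that("profile binning parameters are validated", {
  cc <- noiseless_cell(41)
  a <- analyze_cell(cc)
  bb <- fit_backbone(a$dna, a$mask, a$parb)
  expect_error(profile_along_backbone(cc$stack, bb, bin_um = 0), "bin_um")
  expect_error(profile_along_backbone(cc$stack, bb, bin_um = 0.5,
                                      representative_length_um = 0.3),
               "representative_length")
})
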