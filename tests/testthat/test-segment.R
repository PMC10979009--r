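test_that("no cells are detected in an empty field", {
  blank <- image_stack(array(0, c(32, 32, 1, 1)), "cell")
  expect_identical(nrow(detect_cells(blank)), 0L)
})

test_that("a simulated spheroid is recovered at its true diameter", {
  p <- sim_params(seed = 21)
  cc <- simulate_cell(p)
  rois <- detect_cells(cc$stack)
  expect_equal(nrow(rois), 1L)
  expect_lt(abs(rois$equiv_diameter_um - p$cell_diameter) / p$cell_diameter, 0.1)
  # diameter cross-checked against the truth mask pixel count
  truth_px <- pi * cc$truth$cell_radius_px^2
  truth_diam <- 2 * sqrt(truth_px * (p$pixel_size / 1000)^2 / pi)
  expect_lt(abs(rois$equiv_diameter_um - truth_diam) / truth_diam, 0.1)
})

test_that("two composited cells give two disjoint ROIs", {
  sim <- simulate_condition(sim_params(), 2, seed = 22)
  fov <- composite_field(sim$cells)
  rois <- detect_cells(fov$stack)
  expect_equal(nrow(rois), 2L)
  expect_false(any(rois$mask[[1]] & rois$mask[[2]]))
})

test_that("segmentation masks are invariant to intensity rescaling", {
  cc <- simulate_cell(sim_params(seed = 23))
  r1 <- detect_cells(cc$stack)
  scaled <- cc$stack
  scaled$pixels <- scaled$pixels * 7.3
  r2 <- detect_cells(scaled)
  expect_identical(r1$mask, r2$mask)
})

test_that("roundness screening matches closed-form shape values", {
  # disc: roundness -> 1 up to discretization
  g <- expand.grid(y = 1:50, x = 1:50)
  disc <- matrix((g$x - 25)^2 + (g$y - 25)^2 <= 20^2, 50, 50)
  roi_disc <- roi_from_mask(disc)
  expect_gt(roi_disc$roundness, 0.9)
  expect_equal(nrow(screen_round(roi_disc, 0.85)), 1L)

  # 4:1 rectangle: closed form 4*pi*a*b / (2a + 2b)^2 = 0.503
  rect <- matrix(FALSE, 50, 50)
  rect[21:30, 6:45] <- TRUE   # 10 x 40 px
  roi_rect <- roi_from_mask(rect)
  closed_form <- 4 * pi * 40 * 10 / (2 * (40 + 10))^2
  expect_equal(roi_rect$roundness, closed_form, tolerance = 0.15)
  expect_equal(nrow(screen_round(roi_rect, 0.85)), 0L)

  expect_identical(nrow(screen_round(roi_rect[0, ], 0.85)), 0L)
})

test_that("screen_round is an idempotent filter preserving order", {
  sim <- simulate_condition(sim_params(), 3, seed = 24)
  fov <- composite_field(sim$cells)
  rois <- detect_cells(fov$stack)
  once <- screen_round(rois, 0.85)
  twice <- screen_round(once, 0.85)
  expect_identical(once, twice)
  expect_true(all(once$cell_id %in% rois$cell_id))
  expect_identical(once$cell_id, sort(once$cell_id))
})

test_that("max projection is the per-pixel maximum and identity for one plane", {
  arr <- array(stats::runif(3 * 8 * 8), c(8, 8, 3, 1))
  st <- image_stack(arr, "DNA")
  mp <- max_project(st, "DNA")
  for (y in 1:8) for (x in 1:8) {
    expect_identical(mp[y, x], max(arr[y, x, , 1]))
  }
  one <- image_stack(arr[, , 1, , drop = FALSE], "DNA")
  expect_identical(max_project(one, "DNA"), arr[, , 1, 1])
  expect_error(max_project(one, "nope"), "not found")
})

test_that("single-ParB screening accepts one focus and rejects zero or two", {
  cc1 <- simulate_cell(sim_params(seed = 25))
  r1 <- select_single_chromosome(detect_cells(cc1$stack),
                                 max_project(cc1$stack, "ParB"))
  expect_true(r1$single_parb_pass)

  cc2 <- simulate_cell(sim_params(seed = 26, n_parb_foci = 2))
  r2 <- select_single_chromosome(detect_cells(cc2$stack),
                                 max_project(cc2$stack, "ParB"))
  expect_false(r2$single_parb_pass)

  blank_parb <- matrix(0, 64, 64)
  r3 <- select_single_chromosome(detect_cells(cc1$stack), blank_parb)
  expect_false(r3$single_parb_pass)
})
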