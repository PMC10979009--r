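psf_px <- 120 / 65.35
full_mask <- function(n = 40) matrix(TRUE, n, n)

test_that("a noiseless spot localizes within 0.2 px and a blank mask yields none", {
  img <- render_spots(c(40, 40), 30.4, 17.6, 1e4, psf_px)
  f <- detect_foci(img, full_mask())
  expect_equal(nrow(f), 1L)
  expect_lt(abs(f$x_px - 30.4), 0.2)
  expect_lt(abs(f$y_px - 17.6), 0.2)
  # window truncation and border-ring background make the integrated
  # fraction conservative but dominant
  expect_gt(f$fraction_of_cell_signal, 0.7)
  expect_lte(f$fraction_of_cell_signal, 1)

  expect_identical(nrow(detect_foci(matrix(0, 40, 40), full_mask())), 0L)
})

test_that("the Gaussian-fit refinement matches the centroid on clean spots", {
  img <- render_spots(c(40, 40), 22.7, 13.2, 1e4, psf_px)
  fc <- detect_foci(img, full_mask(), method = "centroid")
  fg <- detect_foci(img, full_mask(), method = "gaussfit")
  expect_lt(abs(fg$x_px - 22.7), 0.2)
  expect_lt(abs(fg$y_px - 13.2), 0.2)
  expect_lt(abs(fg$x_px - fc$x_px), 0.2)
})

test_that("two equal spots three sigma apart split the signal evenly", {
  img <- render_spots(c(40, 40), c(15, 15 + 3 * psf_px), c(20, 20), 1e4, psf_px)
  f <- detect_foci(img, full_mask())
  expect_equal(nrow(f), 2L)
  expect_equal(f$fraction_of_cell_signal[1], 0.5, tolerance = 0.05)
  expect_equal(f$fraction_of_cell_signal[2], 0.5, tolerance = 0.05)
})

test_that("detection is translation-equivariant and fractions are scale-invariant", {
  img <- render_spots(c(48, 48), c(14.3, 30.1), c(25.6, 18.2),
                      c(1e4, 6e3), psf_px)
  f0 <- detect_foci(img, full_mask(48))
  shifted <- matrix(0, 48, 48)
  shifted[4:48, 3:48] <- img[1:45, 1:46]   # shift +3 y, +2 x
  f1 <- detect_foci(shifted, full_mask(48))
  expect_equal(sort(f1$x_px), sort(f0$x_px + 2), tolerance = 1e-6)
  expect_equal(sort(f1$y_px), sort(f0$y_px + 3), tolerance = 1e-6)

  f2 <- detect_foci(img * 37.5, full_mask(48))
  expect_equal(f2$fraction_of_cell_signal, f0$fraction_of_cell_signal,
               tolerance = 1e-6)
  expect_equal(f2$x_px, f0$x_px, tolerance = 1e-9)
})

test_that("psf_sigma must be positive", {
  expect_error(detect_foci(matrix(1, 5, 5), matrix(TRUE, 5, 5),
                           psf_sigma_nm = 0), "psf_sigma")
})

test_that("the 15% fraction filter reproduces hand-computed retention", {
  foci <- tibble::tibble(id = 1:3,
                         fraction_of_cell_signal = c(0.50, 0.30, 0.10))
  kept <- filter_foci_by_fraction(foci, 0.15)
  expect_identical(kept$id, 1:2)
  expect_identical(filter_foci_by_fraction(kept, 0.15), kept)  # idempotent
  none <- tibble::tibble(id = 1:2, fraction_of_cell_signal = c(0, 0))
  expect_identical(nrow(filter_foci_by_fraction(none, 0.15)), 0L)
  expect_identical(filter_foci_by_fraction(foci, 0), foci)     # threshold 0
})

test_that("focus distances follow pixel-size arithmetic and reject cross-cell pairs", {
  f1 <- list(x_px = 0, y_px = 0, cell_id = 1L)
  f2 <- list(x_px = 3, y_px = 4, cell_id = 1L)
  expect_equal(focus_distance(f1, f1), 0)
  expect_equal(focus_distance(f1, f2, pixel_size = 65.35), 5 * 65.35)
  f3 <- list(x_px = 1, y_px = 1, cell_id = 2L)
  expect_error(focus_distance(f1, f3), "different cells")
})

test_that("ori:ter counting pools correctly on constructed tables", {
  toy <- function(ori_per_cell, ter_per_cell, n = 5) {
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      tibble::tibble(
        cell_id = i,
        channel = c(rep("ParB", ori_per_cell), rep("ter", ter_per_cell)),
        fraction_of_cell_signal = c(rep(0.5, ori_per_cell),
                                    rep(0.4, ter_per_cell)))
    }))
  }
  expect_equal(count_and_ratio(toy(2, 1))$ori_ter_ratio, 2)
  r1 <- count_and_ratio(toy(1, 1))
  expect_equal(r1$ori_ter_ratio, 1)
  expect_equal(r1$summary$mean_count, c(1, 1))

  # all ter below the 15% filter -> undefined ratio with warning
  low <- toy(1, 1)
  low$fraction_of_cell_signal[low$channel == "ter"] <- 0.05
  expect_warning(r2 <- count_and_ratio(low), "undefined")
  expect_true(is.na(r2$ori_ter_ratio))

  # per-cell averaging option
  mixed <- dplyr::bind_rows(toy(4, 1, 2), toy(2, 2, 1))
  mixed$cell_id <- rep(1:3, times = c(5, 5, 4))
  expect_equal(count_and_ratio(mixed, per_cell = TRUE)$ori_ter_ratio,
               mean(c(4, 4, 1)))
})
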