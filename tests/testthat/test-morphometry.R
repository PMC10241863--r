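noiseless_series <- function(elong = 100, conv = 30, seg = 2 / 3,
                             duration = 8) {
  gen_landmark_series(elong, conv, seg, duration_h = duration,
                      noise_sd_um = 0, seed = 1)
}

test_that("speed estimators are exact on noiseless linear series", {
  s <- noiseless_series(elong = 100, conv = 30)
  expect_equal(elongation_speed(s), 100, tolerance = 1e-10)
  expect_equal(convergence_speed(s), 30, tolerance = 1e-10)

  static <- gen_landmark_series(0, 0, 0, noise_sd_um = 0, seed = 1)
  expect_equal(elongation_speed(static), 0, tolerance = 1e-10)
  expect_equal(convergence_speed(static), 0, tolerance = 1e-10)
  expect_equal(segmentation_speed(static), 0, tolerance = 1e-10)
})

test_that("one somite pair per 1.5 h gives segmentation speed 2/3", {
  s <- gen_landmark_series(50, 10, 2 / 3, duration_h = 9,
                           frame_interval_h = 1.5, noise_sd_um = 0, seed = 1)
  # counts hit the clock exactly at 1.5 h frames: slope = 2/3
  expect_equal(segmentation_speed(s), 2 / 3, tolerance = 1e-10)
})

test_that("negative speeds (shortening, widening) pass through", {
  s <- gen_landmark_series(-40, -15, 0.4, noise_sd_um = 0, seed = 1,
                           start_width_um = 600)
  expect_equal(elongation_speed(s), -40, tolerance = 1e-10)
  expect_equal(convergence_speed(s), -15, tolerance = 1e-10)
})

test_that("speed estimators are unbiased on noisy generator series", {
  true_e <- 80; true_c <- 25; true_s <- 2 / 3
  n_rep <- 40
  est <- t(vapply(seq_len(n_rep), function(i) {
    s <- gen_landmark_series(true_e, true_c, true_s, noise_sd_um = 5,
                             seed = 500 + i)
    c(elongation_speed(s), convergence_speed(s))
  }, numeric(2)))
  se <- apply(est, 2, sd) / sqrt(n_rep)
  expect_lt(abs(mean(est[, 1]) - true_e), 2 * se[1] + 1e-9)
  expect_lt(abs(mean(est[, 2]) - true_c), 2 * se[2] + 1e-9)
})

test_that("degenerate landmark input is refused", {
  expect_error(landmark_series(c(1, 2), c(0, 0), c(0, 0), c(10, 11), c(0, 0),
                               c(5, 5), c(-5, -5), c(3, 3)),
               class = "vitmech_domain_error")  # inverted pNT walls
  expect_error(landmark_series(c(1, 2), c(0, 0), c(0, 0), c(10, 11), c(0, 0),
                               c(-5, -5), c(5, 5), c(3, 2)),
               class = "vitmech_domain_error")  # somite count decreasing
  s <- noiseless_series()
  one <- s[1, , drop = FALSE]
  class(one) <- class(s)
  expect_error(elongation_speed(one), class = "vitmech_insufficient_data")
})

test_that("fibre density handles saturated, balanced and blank images", {
  all_fg <- matrix(1, 64, 64)
  all_fg[1, 1] <- 0  # one background pixel so a threshold exists
  expect_gt(fibre_density(all_fg, n_rois = 1, roi_size = 64), 0.99)

  half <- matrix(c(rep(0, 2048), rep(1, 2048)), 64, 64)
  expect_equal(as.numeric(fibre_density(half, n_rois = 5, roi_size = 64)),
               0.5, tolerance = 1e-12)

  expect_warning(d <- fibre_density(matrix(0.7, 32, 32)),
                 class = "vitmech_degenerate_image")
  expect_equal(as.numeric(d), 0)
})

test_that("fibre density is invariant under affine intensity rescaling", {
  img <- gen_fibre_image(0.15, size_px = 128, seed = 21)
  a <- fibre_density(img, n_rois = 4, roi_size = 96, seed = 3)
  b <- fibre_density(img * 37 + 11, n_rois = 4, roi_size = 96, seed = 3)
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-12)
})

test_that("whole-image ROI density does not depend on the seed", {
  img <- gen_fibre_image(0.2, size_px = 96, seed = 22)
  a <- fibre_density(img, n_rois = 7, roi_size = 96, seed = 1)
  b <- fibre_density(img, n_rois = 3, roi_size = 96, seed = 99)
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-12)
})

test_that("estimated density increases monotonically with generated coverage", {
  grid <- seq(0.05, 0.4, by = 0.05)
  dens <- vapply(seq_along(grid), function(i) {
    img <- gen_fibre_image(grid[i], size_px = 256, seed = 30 + i)
    as.numeric(fibre_density(img, n_rois = 8, roi_size = 192, seed = 1))
  }, numeric(1))
  expect_equal(cor(dens, grid, method = "spearman"), 1)
})

test_that("inverted-polarity (dark-fibre) images give the same density", {
  img <- gen_fibre_image(0.25, size_px = 128, seed = 23)
  bright <- fibre_density(img, n_rois = 4, roi_size = 128, seed = 2)
  dark <- fibre_density(-img, n_rois = 4, roi_size = 128, seed = 2,
                        fibres_dark = TRUE)
  expect_equal(as.numeric(bright), as.numeric(dark), tolerance = 1e-12)
})
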