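# Spot detection and subpixel Gaussian refinement.

test_that("constant frames yield no candidates", {
  expect_equal(nrow(detect_spots(matrix(100, 40, 40), 100, 130)), 0)
  expect_equal(nrow(detect_spots(matrix(0, 40, 40), 100, 130)), 0)
})

test_that("frames smaller than the filter support are rejected", {
  expect_error(detect_spots(matrix(0, 4, 4), 100, 130), "input error")
})

test_that("a rendered emitter is detected once, within 1 px of truth", {
  frame <- render_ideal_spot(60, x_px = 25.3, y_px = 40.7, photons = 2000,
                             sigma_px = 1.3, background = 10)
  set.seed(42)
  noisy <- matrix(rpois(length(frame), frame), nrow(frame))
  cand <- detect_spots(noisy, 100, 130, snr_threshold = 4)
  expect_equal(nrow(cand), 1)
  expect_lt(abs(cand$j + 0.5 - 25.3), 1)
  expect_lt(abs(cand$i + 0.5 - 40.7), 1)
})

test_that("two well-separated emitters give exactly two candidates", {
  frame <- render_ideal_spot(60, 20.2, 30.4, 2000, 1.3, background = 10) +
    render_ideal_spot(60, 40.2, 30.4, 2000, 1.3)
  set.seed(43)
  noisy <- matrix(rpois(length(frame), frame), nrow(frame))
  cand <- detect_spots(noisy, 100, 130, snr_threshold = 4)
  expect_equal(nrow(cand), 2)
})

test_that("the noiseless fit recovers the centre to < 0.01 px", {
  frame <- render_ideal_spot(60, 25.30, 40.70, 5000, 1.3, background = 5)
  fit <- fit_gaussian_2d(frame, list(i = 40L, j = 25L), window_radius = 5,
                         pixel_size = 100, psf_sigma_guess = 130)
  expect_true(fit$converged)
  expect_lt(abs(fit$x_nm / 100 - 25.30), 0.01)
  expect_lt(abs(fit$y_nm / 100 - 40.70), 0.01)
  expect_lt(abs(fit$intensity - 5000) / 5000, 0.01)
  expect_lt(abs(fit$background - 5), 0.1)
})

test_that("flat or edge-clipped windows are flagged unconverged", {
  flat <- matrix(7, 30, 30)
  fit <- fit_gaussian_2d(flat, list(i = 15L, j = 15L), 5, 100, 130)
  expect_false(fit$converged)
  frame <- render_ideal_spot(30, 2.5, 15.5, 3000, 1.3)
  fit <- fit_gaussian_2d(frame, list(i = 15L, j = 2L), 5, 100, 130)
  expect_false(fit$converged)
  expect_match(fit$reason, "clipped")
})

test_that("localization error stays below 25 nm RMS at 1000 photons", {
  set.seed(77)
  err <- replicate(200, {
    x <- runif(1, 14, 16); y <- runif(1, 14, 16)
    ideal <- render_ideal_spot(30, x, y, 1000, 1.3, background = 10)
    noisy <- matrix(rpois(length(ideal), ideal), 30)
    fit <- fit_gaussian_2d(noisy, list(i = round(y - 0.5), j = round(x - 0.5)),
                           4, 100, 130)
    if (!fit$converged) return(NA_real_)
    sqrt((fit$x_nm - x * 100)^2 + (fit$y_nm - y * 100)^2)
  })
  expect_gt(mean(!is.na(err)), 0.95)
  expect_lt(sqrt(mean(err^2, na.rm = TRUE)), 25)
})

test_that("localization is unbiased at high SNR", {
  set.seed(78)
  dx <- replicate(150, {
    x <- runif(1, 14, 16); y <- runif(1, 14, 16)
    ideal <- render_ideal_spot(30, x, y, 20000, 1.3, background = 10)
    noisy <- matrix(rpois(length(ideal), ideal), 30)
    fit <- fit_gaussian_2d(noisy, list(i = round(y - 0.5), j = round(x - 0.5)),
                           4, 100, 130)
    c(fit$x_nm - x * 100, fit$y_nm - y * 100)
  })
  expect_lt(abs(mean(dx[1, ])), 5)
  expect_lt(abs(mean(dx[2, ])), 5)
})

test_that("rendered movies conserve photons and centre symmetric emitters", {
  cfg <- sim_config(field_size_um = 4, n_frames = 1, photons_mean = 5000,
                    background_photons = 0, read_noise = 0, camera_gain = 2,
                    seed = 6)
  locs <- localization_table("c", "A", 0L, 2050, 2050, 5000, 0)
  stack <- render_movie(locs, cfg, "A")
  frame <- stack[[1]]
  expect_equal(length(stack), 1)
  total_photons <- sum(frame) / cfg$camera_gain
  expect_lt(abs(total_photons - 5000), 3 * sqrt(5000))
  # a symmetric PSF at a pixel centre has its intensity-weighted centroid
  # there; shot noise is averaged out by using the expected image
  ideal <- render_ideal_spot(40, 20.5, 20.5, 5000, 1.3)
  ci0 <- sum((row(ideal) - 0.5) * ideal) / sum(ideal)
  cj0 <- sum((col(ideal) - 0.5) * ideal) / sum(ideal)
  expect_lt(abs(ci0 - 20.5), 0.01)
  expect_lt(abs(cj0 - 20.5), 0.01)
})

test_that("zero emitters and zero background render as all-zero frames", {
  cfg <- sim_config(field_size_um = 3, n_frames = 2, background_photons = 0,
                    read_noise = 0, seed = 1)
  stack <- render_movie(localization_table(), cfg, "A")
  expect_true(all(vapply(stack, function(f) all(f == 0L), logical(1))))
})
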