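# MSD, diffusion fitting, mobility fractions, intensity multiplicities.

test_that("MSD closed forms: constant and ballistic trajectories", {
  const <- make_traj(0:9, rep(5, 10), rep(5, 10))
  curve <- compute_msd(const)
  expect_true(all(curve$msd_nm2 == 0))
  ball <- make_traj(0:3, c(0, 100, 200, 300), rep(0, 4))
  curve <- compute_msd(ball)
  expect_equal(curve$msd_nm2, c(1e4, 4e4, 9e4))
  expect_equal(curve$n_pairs, c(3L, 2L, 1L))
  expect_error(compute_msd(make_traj(0, 1, 1)), "at least 2")
})

test_that("gap frames contribute no displacement pairs", {
  gappy <- make_traj(c(0, 1, 3), c(0, 100, 300), rep(0, 3))
  curve <- compute_msd(gappy)
  expect_equal(curve$lag, c(1L, 2L, 3L))
  expect_equal(curve$n_pairs, c(1L, 1L, 1L))   # lag 1: one pair (0->1) only
})

test_that("diffusion fitting inverts exact MSD lines", {
  lags <- 1:5
  dt <- 0.032
  line <- data.frame(lag = lags, msd_nm2 = 4 * 0.1 * lags * dt * 1e6,
                     n_pairs = rep(100L, 5))
  fit <- fit_diffusion(line, lags, dt)
  expect_equal(fit$D_um2s, 0.1, tolerance = 1e-10)
  expect_equal(fit$loc_error_sigma_hat_nm, 0, tolerance = 1e-5)
  line$msd_nm2 <- line$msd_nm2 + 4 * 15^2      # add localization error
  fit <- fit_diffusion(line, lags, dt)
  expect_equal(fit$D_um2s, 0.1, tolerance = 1e-10)
  expect_equal(fit$loc_error_sigma_hat_nm, 15, tolerance = 1e-6)
})

test_that("negative MSD slopes truncate to D = 0 with a warning", {
  down <- data.frame(lag = 1:3, msd_nm2 = c(300, 200, 100), n_pairs = 10L)
  expect_warning(fit <- fit_diffusion(down, 1:3, 0.032), "truncated")
  expect_equal(fit$D_um2s, 0)
  expect_true(fit$negative_slope)
  expect_error(fit_diffusion(down[1, ], 1:3, 0.032), ">= 2")
})

test_that("pooled MSD of Brownian motion is linear in lag", {
  cfg <- noiseless_config(field_size_um = 15, complex_density = 0.45,
                          complex_mix = c(monomer_A = 1),
                          immobile_fraction = 0, loc_error_sigma = 15,
                          seed = 19)
  trk <- link_trajectories(simulate_cell(cfg)$locs_a)
  fit <- fit_diffusion(pooled_msd(trk), 1:5, cfg$frame_interval)
  expect_gt(fit$r_squared, 0.99)
  expect_lt(abs(fit$D_um2s - cfg$D_free) / cfg$D_free, 0.05)
  expect_lt(abs(fit$loc_error_sigma_hat_nm - 15) / 15, 0.30)
})

test_that("mobility fractions hit the degenerate limits", {
  static <- do.call(rbind, lapply(1:5, function(i)
    make_traj(0:29, rep(i * 1000, 30), rep(0, 30), id = i)))
  mob <- mobility_fractions(static)
  expect_equal(mob$immobile_fraction, 1)

  cfg <- noiseless_config(field_size_um = 12, complex_density = 0.3,
                          complex_mix = c(monomer_A = 1),
                          immobile_fraction = 0, loc_error_sigma = 15,
                          seed = 23)
  trk <- link_trajectories(simulate_cell(cfg)$locs_a)
  mob <- mobility_fractions(trk)
  expect_lte(mob$immobile_fraction, 0.05)
})

test_that("the immobile fraction recovers a 30% ground truth within 5 points", {
  est <- vapply(1:3, function(k) {
    cfg <- sim_config(field_size_um = 15, complex_density = 0.4,
                      complex_mix = c(monomer_A = 0.5, monomer_B = 0.5),
                      immobile_fraction = 0.3, seed = 7000 + k)
    simulate_and_analyze_cell(cfg)$result$immobile_fraction
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.3), 0.05)
})

test_that("multiplicity classification hits the degenerate limits", {
  calls <- data.frame(cotraj_id = 1:4, n_matched = 20L, first_frame = 0L,
                      last_frame = 19L, mean_separation_nm = 30,
                      a_traj = 1:4, b_traj = 1:4,
                      a_intensity = 1000, b_intensity = 1000,
                      a_intensity_initial = 1000,
                      b_intensity_initial = 1000, is_dimer = TRUE)
  expect_equal(oligomer_fraction(calls, 1000, 1000)$oligomer_fraction, 0)
  calls$a_intensity_initial <- 2000
  expect_equal(oligomer_fraction(calls, 1000, 1000)$oligomer_fraction, 1)
  expect_true(is.na(oligomer_fraction(calls, NA, 1000)$oligomer_fraction))
  expect_true(is.na(oligomer_fraction(calls[0, ], 1000,
                                      1000)$oligomer_fraction))
})

test_that("co-tracked complexes diffuse slower than free receptors", {
  cfg <- sim_config(field_size_um = 12, D_free = 0.15, D_dimer = 0.05,
                    complex_mix = cotrackr:::.mix_with_heterodimer(0.4),
                    seed = 29)
  res <- simulate_and_analyze_cell(cfg)
  expect_lt(res$result$D_cotrack_um2s, res$result$D_um2s)
})
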