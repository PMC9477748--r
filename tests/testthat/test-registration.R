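# Channel registration: affine estimation and application.

test_that("identical point sets give the identity transform with zero residual", {
  set.seed(1)
  pts <- matrix(runif(40, 0, 2e4), ncol = 2)
  est <- estimate_affine(pts, pts)
  expect_equal(est$transform$linear, diag(2), tolerance = 1e-10)
  expect_equal(est$transform$translation, c(0, 0), tolerance = 1e-7)
  expect_lt(est$residual_rms, 1e-7)
})

test_that("a pure translation is recovered with opposite sign (B-to-A)", {
  set.seed(2)
  a <- matrix(runif(40, 0, 2e4), ncol = 2)
  b <- sweep(a, 2, c(100, -50), "+")
  est <- estimate_affine(a, b)
  expect_equal(est$transform$translation, c(-100, 50), tolerance = 1e-7)
  expect_lt(est$residual_rms, 1e-7)
})

test_that("a noisy affine is recovered within 1% with residuals near the noise level", {
  truth <- affine2d(matrix(c(1.002, 0.003, -0.002, 0.998), 2, 2),
                    c(120, -80))
  fid <- make_fiducial_set(truth, 50, marker_noise_sigma = 3, seed = 5)
  est <- estimate_affine(fid$points_a, fid$points_b)
  recovered <- invert_affine(est$transform)       # estimate is B->A
  expect_equal(recovered$linear, truth$linear, tolerance = 0.01)
  expect_gt(est$residual_rms, 2)
  expect_lt(est$residual_rms, 5)
})

test_that("degenerate fiducial configurations are rejected", {
  expect_error(estimate_affine(matrix(1:4, 2), matrix(1:4, 2)), ">= 3")
  line <- cbind(1:5 * 100, 1:5 * 200)
  expect_error(estimate_affine(line, line), "collinear")
})

test_that("apply_affine maps coordinates and preserves everything else", {
  tab <- localization_table(rep("c", 3), rep("B", 3), 0:2,
                            c(0, 100, 200), c(0, -100, 50),
                            c(1, 2, 3), c(0, 0, 0))
  expect_equal(apply_affine(tab, affine2d()), tab)
  tr <- affine2d(diag(2), c(10, -20))
  out <- apply_affine(tab, tr)
  expect_equal(out$x_nm, tab$x_nm + 10)
  expect_equal(out$y_nm, tab$y_nm - 20)
  expect_equal(out$intensity, tab$intensity)
  # T then T^-1 is the identity
  tr2 <- affine2d(matrix(c(1.01, 0.02, -0.01, 0.99), 2, 2), c(5, 7))
  back <- apply_affine(apply_affine(tab, tr2), invert_affine(tr2))
  expect_equal(back$x_nm, tab$x_nm, tolerance = 1e-9)
  expect_equal(back$y_nm, tab$y_nm, tolerance = 1e-9)
})

test_that("singular linear parts are rejected", {
  expect_error(affine2d(matrix(c(1, 1, 1, 1), 2, 2)), "singular")
})

test_that("registration rescues co-localization when the chromatic offset exceeds the cutoff", {
  cfg <- sim_config(field_size_um = 10,
                    complex_mix = c(monomer_A = 0.3, monomer_B = 0.3,
                                    heterodimer_AB = 0.4),
                    seed = 55)   # default chromatic offset ~144 nm > 100 nm
  sim <- simulate_cell(cfg)
  mobile_a <- filter_immobile(link_trajectories(sim$locs_a))$mobile
  raw_b <- filter_immobile(link_trajectories(sim$locs_b))$mobile
  reg <- apply_affine(sim$locs_b, invert_affine(cfg$chromatic_transform))
  reg_b <- filter_immobile(link_trajectories(reg))$mobile
  n_raw <- sum(call_dimers(build_cotrajectories(mobile_a, raw_b))$is_dimer)
  n_reg <- sum(call_dimers(build_cotrajectories(mobile_a, reg_b))$is_dimer)
  expect_gt(n_reg, n_raw)
})
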