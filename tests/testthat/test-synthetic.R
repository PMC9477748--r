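# Ground-truth generator and observation model.

test_that("config validation rejects inconsistent parameters", {
  expect_error(sim_config(complex_mix = c(monomer_A = 0.4, monomer_B = 0.4)),
               "sum to 1")
  expect_error(sim_config(field_size_um = -1), "field_size_um")
  expect_error(sim_config(detect_prob = 1.2), "detect_prob")
  expect_error(sim_config(complex_mix = c(pentamer = 1)), "unknown complex")
})

test_that("zero diffusion and zero jitter freeze every particle", {
  cfg <- noiseless_config(field_size_um = 5, n_frames = 20,
                          complex_mix = c(heterodimer_AB = 1),
                          D_free = 0, D_dimer = 0, D_oligomer = 0,
                          immobile_fraction = 0, bond_jitter_sigma = 0,
                          seed = 2)
  truth <- simulate_receptor_truth(cfg)
  expect_true(all(truth$x == truth$x[, 1]))
  expect_true(all(truth$y == truth$y[, 1]))
  # zero jitter: heterodimer members coincide in every frame
  for (cid in unique(truth$particles$complex_id)) {
    rows <- which(truth$particles$complex_id == cid)
    expect_equal(truth$x[rows[1], ], truth$x[rows[2], ])
    expect_equal(truth$y[rows[1], ], truth$y[rows[2], ])
  }
})

test_that("Brownian steps match the closed-form moment 4 D dt", {
  D <- 0.1; dt <- 0.032
  cfg <- noiseless_config(field_size_um = 50, n_frames = 101,
                          complex_density = 0.04,          # 100 particles
                          complex_mix = c(monomer_A = 1), D_free = D,
                          immobile_fraction = 0, bond_jitter_sigma = 0,
                          seed = 31)
  truth <- simulate_receptor_truth(cfg)
  dx <- diff(t(truth$x)) * 1e-3                            # um
  dy <- diff(t(truth$y)) * 1e-3
  sq <- dx^2 + dy^2                                        # 100 x 100 steps
  expected <- 4 * D * dt
  mc_se <- sd(sq) / sqrt(length(sq))
  expect_lt(abs(mean(sq) - expected), 3 * mc_se)
  expect_gt(length(sq), 9999)
})

test_that("complex members share their centre displacement exactly at zero jitter", {
  cfg <- noiseless_config(field_size_um = 10, n_frames = 30,
                          complex_mix = c(ternary_AABB = 1),
                          bond_jitter_sigma = 0, immobile_fraction = 0,
                          seed = 4)
  truth <- simulate_receptor_truth(cfg)
  one <- truth$particles[truth$particles$complex_id ==
                           truth$particles$complex_id[1], ]
  disp <- apply(truth$x[one$particle_id, ], 1, diff)
  expect_true(all(abs(sweep(disp, 1, disp[, 1])) < 1e-9))
})

test_that("noiseless identity observation reproduces true positions", {
  cfg <- noiseless_config(field_size_um = 8, n_frames = 10,
                          complex_mix = c(monomer_A = 0.5, monomer_B = 0.5),
                          immobile_fraction = 0, seed = 9)
  truth <- simulate_receptor_truth(cfg)
  obs <- apply_observation_model(truth, cfg)
  expect_equal(nrow(obs$locs_a) + nrow(obs$locs_b),
               nrow(truth$particles) * cfg$n_frames)
  for (ch in c("A", "B")) {
    locs <- if (ch == "A") obs$locs_a else obs$locs_b
    sel <- truth$particles$channel == ch
    for (t in c(0L, 5L)) {
      got <- sort(locs$x_nm[locs$frame == t])
      want <- sort(truth$x[sel, t + 1])
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("detect_prob = 0 yields empty localization tables", {
  cfg <- noiseless_config(field_size_um = 8, n_frames = 10, seed = 3)
  cfg$detect_prob <- 0
  obs <- apply_observation_model(simulate_receptor_truth(cfg), cfg)
  expect_equal(nrow(obs$locs_a), 0)
  expect_equal(nrow(obs$locs_b), 0)
})

test_that("bleaching lifetimes follow the truncated-geometric mean", {
  p <- 0.02; nf <- 150
  cfg <- noiseless_config(field_size_um = 100, n_frames = nf,
                          complex_density = 0.2,          # 2000 particles
                          complex_mix = c(monomer_A = 1),
                          immobile_fraction = 0, seed = 17)
  cfg$bleach_prob <- p
  truth <- simulate_receptor_truth(cfg)
  obs <- apply_observation_model(truth, cfg)
  lifetimes <- rowSums(obs$emitting)
  expected <- (1 - (1 - p)^nf) / p                        # E[min(Geom(p), nf)]
  mc_se <- sd(lifetimes) / sqrt(length(lifetimes))
  expect_lt(abs(mean(lifetimes) - expected), 3 * mc_se)
})

test_that("same config and seed give identical outputs", {
  cfg <- sim_config(field_size_um = 8, seed = 12)
  s1 <- simulate_cell(cfg)
  s2 <- simulate_cell(cfg)
  expect_identical(s1$locs_a, s2$locs_a)
  expect_identical(s1$locs_b, s2$locs_b)
  expect_identical(s1$truth$x, s2$truth$x)
})

test_that("fiducial sets follow the stated transform", {
  fid <- make_fiducial_set(affine2d(), 20, 0, seed = 1)
  expect_equal(fid$points_a, fid$points_b)
  tr <- affine2d(diag(2), c(100, -50))
  fid <- make_fiducial_set(tr, 20, 0, seed = 1)
  expect_equal(fid$points_b - fid$points_a,
               matrix(rep(c(100, -50), each = 20), ncol = 2))
  expect_error(make_fiducial_set(tr, 2, 0), ">= 3")
})

test_that("same-complex same-channel emitters coalesce with summed intensity", {
  cfg <- noiseless_config(field_size_um = 6, n_frames = 5,
                          complex_mix = c(homodimer_AA = 1),
                          immobile_fraction = 0, bond_jitter_sigma = 0,
                          intensity_cv = 0, seed = 21)
  obs <- apply_observation_model(simulate_receptor_truth(cfg), cfg)
  n_complex <- length(unique(obs$identity$complex_id))
  expect_equal(nrow(obs$locs_a), n_complex * cfg$n_frames)
  expect_true(all(abs(obs$locs_a$intensity - 2 * cfg$photons_mean) < 1e-9))
})
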