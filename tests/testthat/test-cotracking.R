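# Two-colour co-localization, co-trajectory building and dimer calling.

pts <- function(x, y, frame = 0L, channel = "A", traj = NULL) {
  tab <- data.frame(cell_id = "c", channel = channel, frame = frame,
                    x_nm = x, y_nm = y, intensity = 1000, background = 0,
                    stringsAsFactors = FALSE)
  if (!is.null(traj)) tab$trajectory_id <- traj
  tab
}

test_that("frame co-localization respects the 100 nm cutoff", {
  m <- colocalize_frame(pts(0, 0), pts(0, 150), cutoff = 100)
  expect_equal(nrow(m), 0)
  m <- colocalize_frame(pts(0, 0), pts(0, 50), cutoff = 100)
  expect_equal(nrow(m), 1)
  expect_equal(m$separation_nm, 50)
  expect_equal(c(m$x_nm, m$y_nm), c(0, 25))
})

test_that("ambiguous matches minimize total squared separation", {
  # B at (0,60) can pair with A1 (60 nm) or A2 (70 nm): A1 wins
  m <- colocalize_frame(pts(c(0, 0), c(0, 130)), pts(0, 60), cutoff = 100)
  expect_equal(nrow(m), 1)
  expect_equal(m$a_idx, 1)
  expect_equal(m$separation_nm, 60)
  cost <- matrix(c(60^2, 70^2), 2, 1)
  expect_equal(cotrackr:::gated_assignment_cpp(cost, 1e4, 1e4)$total_cost,
               brute_force_assignment_cost(cost, 1e4))
})

test_that("a persistent pair forms one co-trajectory; brief encounters are not dimers", {
  # two tracks moving together for all 150 frames
  set.seed(10)
  path_x <- cumsum(rnorm(150, 0, 50))
  path_y <- cumsum(rnorm(150, 0, 50))
  ta <- pts(path_x, path_y, frame = 0:149, traj = 1L)
  tb <- pts(path_x + 30, path_y, frame = 0:149, channel = "B", traj = 1L)
  ct <- build_cotrajectories(ta, tb)
  expect_equal(length(unique(ct$cotraj_id)), 1)
  calls <- call_dimers(ct)
  expect_equal(calls$n_matched, 150L)
  expect_true(calls$is_dimer)

  # two monomers crossing for 2 frames: never dimer-called
  ax <- seq(0, 4000, length.out = 41)
  bx <- seq(4000, 0, length.out = 41)
  ta <- pts(ax, rep(0, 41), frame = 0:40, traj = 1L)
  tb <- pts(bx, rep(30, 41), frame = 0:40, channel = "B", traj = 1L)
  calls <- call_dimers(build_cotrajectories(ta, tb))
  expect_true(all(!calls$is_dimer))

  # empty input
  expect_equal(nrow(build_cotrajectories(ta[0, ], tb[0, ])), 0)
})

test_that("dimer calling applies the 10-matched-frame persistence rule", {
  ct <- do.call(rbind, lapply(seq_along(c(12, 9, 10)), function(i) {
    n <- c(12, 9, 10)[i]
    data.frame(cotraj_id = i, frame = seq_len(n) - 1L, x_nm = 0, y_nm = 0,
               separation_nm = 40, a_intensity = 1000, b_intensity = 1000,
               a_traj = i, b_traj = i)
  }))
  calls <- call_dimers(ct)
  expect_equal(sum(calls$is_dimer), 2)
  expect_false(calls$is_dimer[calls$n_matched == 9])
  expect_equal(nrow(call_dimers(ct[0, ])), 0)
})

test_that("relative dimerization normalizes by the smaller track count", {
  expect_equal(relative_dimerization(0, 30, 40), 0)
  expect_equal(relative_dimerization(20, 20, 20), 1)
  expect_equal(relative_dimerization(5, 50, 25), 0.2)
  expect_true(is.na(relative_dimerization(0, 0, 40)))
  expect_true(is.na(relative_dimerization(3, 10, 0)))
})

test_that("the dimer count is invariant under global rotation and translation", {
  cfg <- sim_config(field_size_um = 10,
                    complex_mix = cotrackr:::.mix_with_heterodimer(0.3),
                    seed = 91)
  sim <- simulate_cell(cfg)
  reg_b <- apply_affine(sim$locs_b, invert_affine(cfg$chromatic_transform))
  prep <- function(locs) filter_immobile(link_trajectories(locs))$mobile
  n0 <- sum(call_dimers(build_cotrajectories(prep(sim$locs_a),
                                             prep(reg_b)))$is_dimer)
  th <- 0.7
  rigid <- affine2d(matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2),
                    c(5000, -3000))
  n1 <- sum(call_dimers(build_cotrajectories(
    prep(apply_affine(sim$locs_a, rigid)),
    prep(apply_affine(reg_b, rigid))))$is_dimer)
  expect_equal(n1, n0)
  expect_gt(n0, 0)
})

test_that("dimer calls are monotone in the co-localization cutoff", {
  cfg <- sim_config(field_size_um = 10,
                    complex_mix = cotrackr:::.mix_with_heterodimer(0.3),
                    seed = 92)
  sim <- simulate_cell(cfg)
  reg_b <- apply_affine(sim$locs_b, invert_affine(cfg$chromatic_transform))
  ma <- filter_immobile(link_trajectories(sim$locs_a))$mobile
  mb <- filter_immobile(link_trajectories(reg_b))$mobile
  counts <- vapply(c(5, 25, 50, 100, 200), function(cut) {
    p <- dimer_params(cutoff_radius = cut)
    sum(call_dimers(build_cotrajectories(ma, mb, p), p)$is_dimer)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_lt(counts[1], counts[5])   # tiny cutoff admits almost nothing
})

test_that("higher ground-truth dimer proportions give higher estimates", {
  est <- vapply(c(0.1, 0.3), function(p) {
    cfg <- sim_config(field_size_um = 12,
                      complex_mix = cotrackr:::.mix_with_heterodimer(p),
                      seed = 93)           # same seed protocol, same density
    simulate_and_analyze_cell(cfg)$result$relative_dimerization
  }, numeric(1))
  expect_lt(est[1], est[2])
})
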