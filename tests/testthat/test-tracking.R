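# Trajectory linking, gap closing, and immobile filtering.

loc_rows <- function(frame, x, y, channel = "A") {
  localization_table(rep("c", length(frame)), rep(channel, length(frame)),
                     frame, x, y, rep(1000, length(frame)),
                     rep(0, length(frame)))
}

test_that("a slowly stepping particle forms one trajectory over all frames", {
  tab <- loc_rows(0:19, seq(0, 190, by = 10), rep(0, 20))
  trk <- link_trajectories(tab, max_disp = 500, max_gap = 0)
  expect_equal(length(unique(trk$trajectory_id)), 1)
  expect_equal(trk$frame, 0:19)
})

test_that("assignment prefers the low-cost pairing over the swapped one", {
  tab <- loc_rows(c(0, 0, 1, 1), c(0, 1000, 10, 990), c(0, 0, 0, 0))
  trk <- link_trajectories(tab, max_disp = 500, max_gap = 0)
  # correct links: (0,0)->(10,0) and (1000,0)->(990,0); cost 200 nm^2
  id_near0 <- trk$trajectory_id[trk$frame == 0 & trk$x_nm == 0]
  expect_equal(trk$trajectory_id[trk$frame == 1 & trk$x_nm == 10], id_near0)
  id_near1000 <- trk$trajectory_id[trk$frame == 0 & trk$x_nm == 1000]
  expect_equal(trk$trajectory_id[trk$frame == 1 & trk$x_nm == 990],
               id_near1000)
  # total assignment cost equals the enumerated minimum
  cost <- outer(c(0, 1000), c(10, 990), function(a, b) (a - b)^2)
  res <- cotrackr:::gated_assignment_cpp(cost, 500^2, 500^2)
  expect_equal(res$total_cost, brute_force_assignment_cost(cost, 500^2))
  expect_equal(res$total_cost, 200)
})

test_that("a single missing frame is bridged by gap closing", {
  frames <- c(0:4, 6:10)
  tab <- loc_rows(frames, frames * 10, rep(0, 10))
  trk <- link_trajectories(tab, max_disp = 500, max_gap = 1)
  expect_equal(length(unique(trk$trajectory_id)), 1)
  st <- trajectory_stats(trk)
  expect_equal(st$n_obs, 10L)
  expect_equal(st$lifetime, 11L)
  # with max_gap = 0 the same input fragments into two trajectories
  trk0 <- link_trajectories(tab, max_disp = 500, max_gap = 0)
  expect_equal(length(unique(trk0$trajectory_id)), 2)
})

test_that("gap displacement tolerance scales with sqrt(gap + 1)", {
  # jump of 600 nm over a 1-frame gap: allowed (600 < 500 * sqrt(2))
  tab <- loc_rows(c(0, 1, 3, 4), c(0, 10, 610, 620), rep(0, 4))
  trk <- link_trajectories(tab, max_disp = 500, max_gap = 1)
  expect_equal(length(unique(trk$trajectory_id)), 1)
  # jump of 800 nm over the same gap: forbidden (800 > 500 * sqrt(2))
  tab2 <- loc_rows(c(0, 1, 3, 4), c(0, 10, 810, 820), rep(0, 4))
  trk2 <- link_trajectories(tab2, max_disp = 500, max_gap = 1)
  expect_equal(length(unique(trk2$trajectory_id)), 2)
})

test_that("per-frame assignment cost matches brute force on random instances", {
  set.seed(123)
  for (rep in 1:200) {
    n <- sample(0:5, 1)
    m <- sample(0:5, 1)
    cost <- matrix(runif(n * m, 0, 1e5), n, m)
    gate <- runif(1, 1e4, 8e4)
    res <- cotrackr:::gated_assignment_cpp(cost, gate, gate)
    expect_equal(res$total_cost, brute_force_assignment_cost(cost, gate),
                 tolerance = 1e-9)
    # one-to-one: no column used twice
    used <- res$match[res$match > 0]
    expect_equal(anyDuplicated(used), 0)
  }
})

test_that("every localization is used at most once and frames increase", {
  cfg <- sim_config(field_size_um = 10, seed = 44)
  locs <- simulate_cell(cfg)$locs_a
  trk <- link_trajectories(locs)
  expect_equal(nrow(trk), nrow(locs))
  for (tr in split(trk, trk$trajectory_id)) {
    expect_true(all(diff(tr$frame) >= 1))
    expect_true(all(diff(tr$frame) <= 2))     # max_gap = 1
  }
})

test_that("without blinking each emitting particle yields exactly one track", {
  cfg <- noiseless_config(field_size_um = 12, complex_density = 0.1,
                          complex_mix = c(monomer_A = 1),
                          immobile_fraction = 0, seed = 66)
  sim <- simulate_cell(cfg)
  trk <- link_trajectories(sim$locs_a, max_disp = 500, max_gap = 0)
  n_particles <- sum(sim$truth$particles$labeled &
                       sim$truth$particles$channel == "A")
  expect_equal(length(unique(trk$trajectory_id)), n_particles)
})

test_that("radius-of-gyration filtering separates mobility classes", {
  static <- make_traj(0:19, rep(100, 20), rep(100, 20))
  out <- filter_immobile(static, rg_threshold = 75, min_lifetime = 10)
  expect_equal(nrow(out$mobile), 0)
  expect_equal(nrow(out$immobile), 20)
  expect_equal(out$stats$radius_gyration_nm, 0)

  # Brownian tracks at D = 0.1 um^2/s are almost always retained as mobile
  cfg <- noiseless_config(field_size_um = 15, complex_density = 0.5,
                          complex_mix = c(monomer_A = 1),
                          immobile_fraction = 0, loc_error_sigma = 15,
                          seed = 13)
  trk <- link_trajectories(simulate_cell(cfg)$locs_a)
  flt <- filter_immobile(trk)
  retained <- length(unique(flt$mobile$trajectory_id)) /
    length(unique(trk$trajectory_id))
  expect_gte(retained, 0.95)
})

test_that("mobility classification is >= 95% accurate against ground truth", {
  # density within the single-molecule regime the linker is validated for
  cfg <- sim_config(field_size_um = 15, complex_density = 0.25,
                    complex_mix = c(monomer_A = 1), immobile_fraction = 0.3,
                    label_prob_a = 1, detect_prob = 1, blink_off_prob = 0,
                    bleach_prob = 0, false_positive_rate = 0,
                    loc_error_sigma = 15, seed = 14)
  sim <- simulate_cell(cfg)
  ids <- sim$identity
  locs <- sim$locs_a
  locs$complex_id <- ids$complex_id[ids$channel == "A"]
  trk <- link_trajectories(locs)
  flt <- filter_immobile(trk)
  truth_mob <- function(trajs) {
    cid <- vapply(split(trajs$complex_id, trajs$trajectory_id), function(v)
      as.integer(names(which.max(table(v)))), integer(1))
    sim$truth$particles$mobility[match(cid, sim$truth$particles$complex_id)]
  }
  correct <- sum(truth_mob(flt$mobile) == "mobile") +
    sum(truth_mob(flt$immobile) == "immobile")
  total <- length(unique(trk$trajectory_id))
  expect_gte(correct / total, 0.95)
})
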