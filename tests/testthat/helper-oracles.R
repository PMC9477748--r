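# Shared fixtures and independent oracles used across test files.

# Brute-force partial-matching oracle: minimum of sum(linked costs) +
# dummy_cost per unmatched row/column over ALL feasible partial matchings
# with links restricted to cost <= gate. Exponential; for tiny instances.
brute_force_assignment_cost <- function(cost, gate, dummy_cost = gate) {
  n <- nrow(cost)
  m <- ncol(cost)
  best <- Inf
  recurse <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > n) {
      best <<- min(best, acc + dummy_cost * (m - sum(used)))
      return()
    }
    recurse(i + 1, used, acc + dummy_cost)          # row i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && is.finite(cost[i, j]) && cost[i, j] <= gate) {
        used[j] <- TRUE
        recurse(i + 1, used, acc + cost[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1, rep(FALSE, m), 0)
  best
}

# Double-loop ECDF oracle for the two-sample KS statistic: evaluates both
# empirical CDFs at every observation of both samples.
brute_force_ks_D <- function(x, y) {
  d <- 0
  for (v in c(x, y)) {
    f1 <- sum(x <= v) / length(x)
    f2 <- sum(y <= v) / length(y)
    d <- max(d, abs(f1 - f2))
  }
  d
}

# Minimal noise-free observation settings on top of sim_config(): every
# labelled particle detected in every frame at its true position. Any
# default here can still be overridden by the caller.
noiseless_config <- function(...) {
  args <- utils::modifyList(
    list(label_prob_a = 1, label_prob_b = 1, detect_prob = 1,
         blink_off_prob = 0, blink_on_prob = 0, bleach_prob = 0,
         loc_error_sigma = 0, false_positive_rate = 0,
         chromatic_transform = affine2d()),
    list(...))
  do.call(sim_config, args)
}

# A single-trajectory table from bare vectors.
make_traj <- function(frame, x, y, intensity = rep(1000, length(frame)),
                      id = 1L, channel = "A") {
  data.frame(trajectory_id = id, cell_id = "t", channel = channel,
             frame = as.integer(frame), x_nm = x, y_nm = y,
             intensity = intensity, background = 0,
             stringsAsFactors = FALSE)
}

# Pixel-integrated Gaussian spot rendered deterministically (no noise):
# independent reconstruction of the camera model for detection tests.
render_ideal_spot <- function(n_px, x_px, y_px, photons, sigma_px,
                              background = 0) {
  xe <- 0:n_px
  fx <- diff(pnorm(xe, mean = x_px, sd = sigma_px))
  fy <- diff(pnorm(xe, mean = y_px, sd = sigma_px))
  outer(fy, fx) * photons + background
}
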