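# Synthetic dual-colour single-molecule data: ground-truth receptor
# complexes diffusing in a membrane patch, a fluorescence observation model
# (labelling, blinking, bleaching, localization error, chromatic offset,
# false positives), and fiducial calibration sets.

# Deterministic seed derivation so each stage / cell gets an independent,
# reproducible stream from one run seed. Lehmer-style step keeps all
# arithmetic exact in doubles.
derive_seed <- function(seed, stage, index = 0L) {
  m <- 2147483647
  a <- (as.numeric(seed) %% m + m) %% m
  a <- (a * 48271) %% m
  h <- sum(utf8ToInt(stage)) %% m
  as.integer((a + h * 7919 + as.numeric(index) * 104729) %% m)
}

.reflect <- function(x, lo, hi) {
  # reflect coordinates into [lo, hi] (period 2*(hi-lo))
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  y <- ifelse(y > w, 2 * w - y, y)
  y + lo
}

#' Simulate ground-truth receptor complex trajectories
#'
#' Complexes are placed uniformly in a square membrane patch and their
#' centres perform 2D Brownian motion with per-axis per-step variance
#' \eqn{2 D \Delta t} (D set by complex type: monomer, dimer or larger;
#' zero for the immobile class), reflected at the field boundaries. Each
#' member protomer sits at the complex centre plus independent per-frame
#' Gaussian jitter (`bond_jitter_sigma` per axis). Complex composition is
#' fixed for the whole movie: the 4.8 s acquisitions quantify equilibrium
#' dimerization levels, not binding kinetics.
#'
#' @param config A [sim_config()].
#' @return A `ground_truth` list: `particles` (one row per protomer:
#'   `particle_id`, `complex_id`, `complex_type`, `species`, `channel`,
#'   `labeled`, `mobility`, `D`), position matrices `x`, `y`
#'   (particles x frames, nm), and the `config`.
#' @export
simulate_receptor_truth <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "truth"))
  L <- config$field_size_um * 1000          # field side, nm
  nf <- config$n_frames
  n_complex <- max(0L, round(config$complex_density * config$field_size_um^2))

  if (n_complex == 0) {
    particles <- data.frame(particle_id = integer(), complex_id = integer(),
                            complex_type = character(), species = character(),
                            channel = character(), labeled = logical(),
                            mobility = character(), D = numeric(),
                            stringsAsFactors = FALSE)
    return(structure(list(particles = particles,
                          x = matrix(0, 0, nf), y = matrix(0, 0, nf),
                          config = config), class = "ground_truth"))
  }

  types <- sample(COMPLEX_TYPES, n_complex, replace = TRUE,
                  prob = config$complex_mix)
  mobility <- ifelse(runif(n_complex) < config$immobile_fraction,
                     "immobile", "mobile")
  n_members <- vapply(.complex_members[types], length, integer(1))
  D_type <- ifelse(n_members == 1, config$D_free,
                   ifelse(n_members == 2, config$D_dimer, config$D_oligomer))
  D <- ifelse(mobility == "immobile", 0, D_type)

  # complex centre paths (nm)
  step_sd <- sqrt(2 * D * config$frame_interval) * 1000
  cx <- matrix(0, n_complex, nf)
  cy <- matrix(0, n_complex, nf)
  cx[, 1] <- runif(n_complex, 0, L)
  cy[, 1] <- runif(n_complex, 0, L)
  if (nf > 1) {
    for (t in 2:nf) {
      cx[, t] <- .reflect(cx[, t - 1] + rnorm(n_complex, 0, step_sd), 0, L)
      cy[, t] <- .reflect(cy[, t - 1] + rnorm(n_complex, 0, step_sd), 0, L)
    }
  }

  # expand complexes into member protomers
  complex_id <- rep(seq_len(n_complex), n_members)
  species <- unlist(.complex_members[types], use.names = FALSE)
  n_part <- length(complex_id)
  if (config$label_scheme == "by_species") {
    channel <- species
  } else {
    channel <- ifelse(runif(n_part) < 0.5, "A", "B")
  }
  label_p <- ifelse(channel == "A", config$label_prob_a, config$label_prob_b)
  labeled <- runif(n_part) < label_p

  x <- cx[complex_id, , drop = FALSE]
  y <- cy[complex_id, , drop = FALSE]
  multi <- n_members[complex_id] > 1          # monomers sit at the centre
  if (config$bond_jitter_sigma > 0 && any(multi)) {
    nmulti <- sum(multi)
    x[multi, ] <- x[multi, ] +
      matrix(rnorm(nmulti * nf, 0, config$bond_jitter_sigma), nmulti, nf)
    y[multi, ] <- y[multi, ] +
      matrix(rnorm(nmulti * nf, 0, config$bond_jitter_sigma), nmulti, nf)
  }
  x <- .reflect(x, 0, L)
  y <- .reflect(y, 0, L)

  particles <- data.frame(
    particle_id = seq_len(n_part), complex_id = complex_id,
    complex_type = types[complex_id], species = species, channel = channel,
    labeled = labeled, mobility = mobility[complex_id], D = D[complex_id],
    stringsAsFactors = FALSE)

  structure(list(particles = particles, x = x, y = y, config = config),
            class = "ground_truth")
}

#' Apply the fluorescence observation model to ground truth
#'
#' Each labelled protomer carries a fluorophore that follows a two-state
#' blinking chain (per-frame `blink_off_prob` / `blink_on_prob`) with
#' irreversible bleaching (`bleach_prob`), starting in the ON state. An ON
#' fluorophore is localized in a frame with probability `detect_prob`.
#' Fluorophores of the same complex in the same channel are closer than the
#' diffraction limit and therefore coalesce into a single localization whose
#' intensity is the sum of the member intensities — this is what makes
#' higher-order complexes brighter than monomers. Positions are perturbed by
#' isotropic Gaussian localization error; channel-B coordinates are passed
#' through the chromatic transform first; spurious detections are added
#' uniformly at `false_positive_rate` per frame per channel.
#'
#' @param truth A `ground_truth` from [simulate_receptor_truth()].
#' @param config The same [sim_config()]; defaults to the one stored in
#'   `truth`.
#' @param cell_id Cell identifier stamped on the localization tables.
#' @return A list: `locs_a`, `locs_b` (localization tables), `identity`
#'   (one row per localization: `channel`, `row` in that channel's table,
#'   `frame`, `complex_id`, `complex_type`, `n_members`; `complex_id` is
#'   `NA` for false positives), `emitting` (particles x frames logical
#'   matrix: ON and detected this frame) and `alive` (particles x frames:
#'   labelled and not yet bleached, i.e. still capable of emitting).
#' @export
apply_observation_model <- function(truth, config = truth$config,
                                    cell_id = "cell1") {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "observe"))
  P <- truth$particles
  nf <- config$n_frames
  n_part <- nrow(P)
  L <- config$field_size_um * 1000

  # photophysics: ON/OFF/BLEACHED chain per labelled particle
  emitting <- matrix(FALSE, n_part, nf)
  alive <- matrix(FALSE, n_part, nf)
  if (n_part > 0) {
    state <- ifelse(P$labeled, 1L, 0L)       # 1 ON, 0 permanently dark, -1 OFF, 2 bleached
    for (t in seq_len(nf)) {
      on <- state == 1L
      alive[, t] <- state == 1L | state == -1L
      emitting[, t] <- on & (runif(n_part) < config$detect_prob)
      u <- runif(n_part)
      # transitions applied after the frame
      bleach <- on & (u < config$bleach_prob)
      goes_off <- on & !bleach &
        (runif(n_part) < config$blink_off_prob)
      comes_on <- (state == -1L) & (runif(n_part) < config$blink_on_prob)
      state[bleach] <- 2L
      state[goes_off] <- -1L
      state[comes_on] <- 1L
    }
  }

  int_sd <- config$intensity_cv * config$photons_mean
  bg <- config$background_photons * config$camera_gain

  rows <- list()
  idmap <- list()
  for (ch in c("A", "B")) {
    sel <- which(P$channel == ch)
    recs <- list()
    for (t in seq_len(nf)) {
      em <- sel[emitting[sel, t]]
      if (length(em) > 0) {
        # coalesce emitters of the same complex (sub-diffraction separation)
        grp <- split(em, P$complex_id[em])
        gx <- vapply(grp, function(i) mean(truth$x[i, t]), numeric(1))
        gy <- vapply(grp, function(i) mean(truth$y[i, t]), numeric(1))
        gint <- vapply(grp, function(i)
          sum(pmax(rnorm(length(i), config$photons_mean, int_sd), 0)),
          numeric(1))
        cid <- as.integer(names(grp))
        recs[[length(recs) + 1L]] <- data.frame(
          frame = t - 1L, x_nm = gx, y_nm = gy, intensity = gint,
          complex_id = cid, n_members = lengths(grp),
          stringsAsFactors = FALSE)
      }
      nfp <- rpois(1, config$false_positive_rate)
      if (nfp > 0) {
        recs[[length(recs) + 1L]] <- data.frame(
          frame = t - 1L, x_nm = runif(nfp, 0, L), y_nm = runif(nfp, 0, L),
          intensity = pmax(rnorm(nfp, config$photons_mean, int_sd), 0),
          complex_id = NA_integer_, n_members = 1L, stringsAsFactors = FALSE)
      }
    }
    tab <- if (length(recs) > 0) do.call(rbind, recs) else
      data.frame(frame = integer(), x_nm = numeric(), y_nm = numeric(),
                 intensity = numeric(), complex_id = integer(),
                 n_members = integer())
    if (ch == "B" && nrow(tab) > 0) {
      xy <- transform_points(config$chromatic_transform,
                             cbind(tab$x_nm, tab$y_nm))
      tab$x_nm <- xy[, 1]
      tab$y_nm <- xy[, 2]
    }
    if (config$loc_error_sigma > 0 && nrow(tab) > 0) {
      tab$x_nm <- tab$x_nm + rnorm(nrow(tab), 0, config$loc_error_sigma)
      tab$y_nm <- tab$y_nm + rnorm(nrow(tab), 0, config$loc_error_sigma)
    }
    loc <- localization_table(cell_id = rep(cell_id, nrow(tab)),
                              channel = rep(ch, nrow(tab)),
                              frame = tab$frame, x_nm = tab$x_nm,
                              y_nm = tab$y_nm, intensity = tab$intensity,
                              background = rep(bg, nrow(tab)))
    rows[[ch]] <- loc
    idmap[[ch]] <- data.frame(
      channel = rep(ch, nrow(tab)), row = seq_len(nrow(tab)),
      frame = tab$frame, complex_id = tab$complex_id,
      complex_type = ifelse(is.na(tab$complex_id), NA_character_,
                            truth$particles$complex_type[
                              match(tab$complex_id,
                                    truth$particles$complex_id)]),
      n_members = tab$n_members, stringsAsFactors = FALSE)
  }

  list(locs_a = rows$A, locs_b = rows$B,
       identity = rbind(idmap$A, idmap$B), emitting = emitting,
       alive = alive)
}

#' Generate a fiducial-marker calibration set
#'
#' Channel-A marker positions are uniform in the field; channel-B positions
#' are the chromatic transform of channel A plus isotropic Gaussian noise.
#'
#' @param transform [affine2d] mapping channel-A to channel-B coordinates.
#' @param n_markers Number of markers (>= 3; an affine is not identifiable
#'   below that).
#' @param marker_noise_sigma Per-axis noise SD (nm).
#' @param seed Integer seed.
#' @param field_size_um Field side (um).
#' @return A list with `points_a` and `points_b` (n x 2 matrices, nm).
#' @export
make_fiducial_set <- function(transform, n_markers, marker_noise_sigma = 0,
                              seed = 1L, field_size_um = 20) {
  if (n_markers < 3)
    stop("n_markers must be >= 3: an affine transform is not identifiable")
  set.seed(derive_seed(seed, "fiducial"))
  L <- field_size_um * 1000
  a <- cbind(runif(n_markers, 0, L), runif(n_markers, 0, L))
  b <- transform_points(transform, a)
  if (marker_noise_sigma > 0)
    b <- b + matrix(rnorm(2 * n_markers, 0, marker_noise_sigma), ncol = 2)
  list(points_a = a, points_b = b)
}
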