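# Simulation configuration: the study conditions of a synthetic dual-colour
# single-molecule movie. Units follow microscopy convention: lengths in nm
# unless the name says um, times in seconds, diffusion constants in um^2/s.

#' Complex species modelled by the simulator
#'
#' Seven complex types cover the labelling topologies used to measure
#' receptor homo- and heterodimerization: free monomers of either receptor,
#' homodimers, the heterodimer, the 2:2 ternary complex, and a hexameric
#' (6-protomer) array that represents higher-order clustering.
#'
#' @format Character vector of the seven complex type names.
#' @export
COMPLEX_TYPES <- c("monomer_A", "monomer_B", "homodimer_AA", "homodimer_BB",
                   "heterodimer_AB", "ternary_AABB", "hexamer_B6")

# receptor species composition of each complex type
.complex_members <- list(
  monomer_A      = "A",
  monomer_B      = "B",
  homodimer_AA   = c("A", "A"),
  homodimer_BB   = c("B", "B"),
  heterodimer_AB = c("A", "B"),
  ternary_AABB   = c("A", "A", "B", "B"),
  hexamer_B6     = rep("B", 6)
)

#' Create a simulation configuration
#'
#' Defines a synthetic membrane patch imaged by dual-colour TIRF: Brownian
#' receptor complexes with an immobile subpopulation, two-state blinking and
#' irreversible bleaching, localization error, a chromatic offset on channel
#' B, and optional camera rendering parameters. Defaults reproduce the
#' acquisition regime of the live-cell experiments the pipeline targets:
#' 150 frames at 32 ms per frame.
#'
#' @param field_size_um Side of the square membrane patch (um).
#' @param n_frames Number of frames per movie.
#' @param frame_interval Frame interval (s).
#' @param complex_density Total complexes per um^2 (all types together).
#' @param complex_mix Named numeric vector of proportions over
#'   [COMPLEX_TYPES]; must be non-negative and sum to 1.
#' @param D_free,D_dimer,D_oligomer Diffusion constants (um^2/s) for
#'   monomers, dimers (2 protomers) and larger complexes respectively.
#' @param immobile_fraction Proportion of complexes that are immobile.
#' @param bond_jitter_sigma Per-axis SD (nm) of each protomer's position
#'   about its complex centre.
#' @param label_scheme `"by_species"` images receptor A in channel A and
#'   receptor B in channel B (heterodimer measurement); `"split"` assigns
#'   every labelled protomer to channel A or B with probability 1/2 each
#'   (two-colour labelling of a single receptor, used to measure
#'   homodimerization).
#' @param label_prob_a,label_prob_b Labelling probability per protomer for
#'   each channel's fluorophore.
#' @param detect_prob Per-frame probability that an emitting fluorophore is
#'   actually localized.
#' @param blink_off_prob,blink_on_prob Per-frame off/on transition
#'   probabilities of the two-state blinking chain.
#' @param bleach_prob Per-frame irreversible bleaching probability.
#' @param loc_error_sigma Per-axis localization error SD (nm).
#' @param false_positive_rate Expected spurious localizations per frame per
#'   channel (uniform over the field).
#' @param chromatic_transform [affine2d] mapping true (channel-A frame)
#'   coordinates to channel-B camera coordinates.
#' @param photons_mean Mean photon count of a single emitter per frame.
#' @param intensity_cv Coefficient of variation of per-emitter intensity.
#' @param psf_sigma PSF standard deviation (nm).
#' @param pixel_size Camera pixel size (nm).
#' @param camera_gain Counts per photon.
#' @param read_noise Read noise SD (counts).
#' @param background_photons Mean background photons per pixel per frame.
#' @param seed Integer seed; every stochastic stage derives its stream
#'   from it.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(field_size_um = 20,
                       n_frames = 150,
                       frame_interval = 0.032,
                       complex_density = 0.2,
                       complex_mix = c(monomer_A = 0.5, monomer_B = 0.5),
                       D_free = 0.10,
                       D_dimer = 0.07,
                       D_oligomer = 0.04,
                       immobile_fraction = 0.1,
                       bond_jitter_sigma = 10,
                       label_scheme = c("by_species", "split"),
                       label_prob_a = 0.85,
                       label_prob_b = 0.85,
                       detect_prob = 0.9,
                       blink_off_prob = 0.05,
                       blink_on_prob = 0.3,
                       bleach_prob = 0.005,
                       loc_error_sigma = 15,
                       false_positive_rate = 0.2,
                       chromatic_transform = default_chromatic_transform(),
                       photons_mean = 1500,
                       intensity_cv = 0.2,
                       psf_sigma = 130,
                       pixel_size = 100,
                       camera_gain = 2,
                       read_noise = 1.5,
                       background_photons = 10,
                       seed = 1L) {
  label_scheme <- match.arg(label_scheme)
  mix <- rep(0, length(COMPLEX_TYPES))
  names(mix) <- COMPLEX_TYPES
  if (length(complex_mix) > 0) {
    bad <- setdiff(names(complex_mix), COMPLEX_TYPES)
    if (length(bad) > 0)
      stop("unknown complex type(s) in complex_mix: ", paste(bad, collapse = ", "))
    mix[names(complex_mix)] <- as.numeric(complex_mix)
  }
  cfg <- list(
    field_size_um = field_size_um, n_frames = as.integer(n_frames),
    frame_interval = frame_interval, complex_density = complex_density,
    complex_mix = mix, D_free = D_free, D_dimer = D_dimer,
    D_oligomer = D_oligomer, immobile_fraction = immobile_fraction,
    bond_jitter_sigma = bond_jitter_sigma, label_scheme = label_scheme,
    label_prob_a = label_prob_a, label_prob_b = label_prob_b,
    detect_prob = detect_prob, blink_off_prob = blink_off_prob,
    blink_on_prob = blink_on_prob, bleach_prob = bleach_prob,
    loc_error_sigma = loc_error_sigma,
    false_positive_rate = false_positive_rate,
    chromatic_transform = chromatic_transform,
    photons_mean = photons_mean, intensity_cv = intensity_cv,
    psf_sigma = psf_sigma, pixel_size = pixel_size,
    camera_gain = camera_gain, read_noise = read_noise,
    background_photons = background_photons, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg A `sim_config` object.
#' @return `cfg`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.finite(cfg$field_size_um) || cfg$field_size_um <= 0)
    stop("configuration error: field_size_um must be > 0")
  if (cfg$n_frames < 1) stop("configuration error: n_frames must be >= 1")
  if (!is.finite(cfg$frame_interval) || cfg$frame_interval <= 0)
    stop("configuration error: frame_interval must be > 0")
  mix <- cfg$complex_mix
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    stop("configuration error: complex_mix proportions must be >= 0 and sum to 1")
  probs <- c(immobile_fraction = cfg$immobile_fraction,
             label_prob_a = cfg$label_prob_a, label_prob_b = cfg$label_prob_b,
             detect_prob = cfg$detect_prob,
             blink_off_prob = cfg$blink_off_prob,
             blink_on_prob = cfg$blink_on_prob, bleach_prob = cfg$bleach_prob)
  out <- probs < 0 | probs > 1
  if (any(out))
    stop("configuration error: not in [0,1]: ",
         paste(names(probs)[out], collapse = ", "))
  for (nm in c("D_free", "D_dimer", "D_oligomer", "bond_jitter_sigma",
               "loc_error_sigma", "false_positive_rate", "photons_mean",
               "intensity_cv", "psf_sigma", "pixel_size", "camera_gain",
               "read_noise", "background_photons"))
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 0)
      stop("configuration error: ", nm, " must be >= 0")
  if (cfg$pixel_size <= 0 || cfg$psf_sigma <= 0)
    stop("configuration error: pixel_size and psf_sigma must be > 0")
  if (!inherits(cfg$chromatic_transform, "affine2d"))
    stop("configuration error: chromatic_transform must be an affine2d")
  invisible(cfg)
}

#' Default chromatic transform of the simulated dual-view splitter
#'
#' Translation of (120, -80) nm plus a 0.1 % isotropic scale, representative
#' of the chromatic offset between the two halves of an image splitter.
#'
#' @return An [affine2d] mapping channel-A coordinates to channel-B
#'   coordinates.
#' @export
default_chromatic_transform <- function() {
  affine2d(matrix(c(1.001, 0, 0, 1.001), 2, 2), c(120, -80))
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar fields override the defaults of [sim_config()]; `complex_mix` is
#' given as a named mapping and `chromatic_transform` as six numbers
#' (row-major 2x2 linear part, then the translation, nm).
#'
#' @param path Path to a YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$complex_mix)) raw$complex_mix <- unlist(raw$complex_mix)
  if (!is.null(raw$chromatic_transform)) {
    v <- as.numeric(unlist(raw$chromatic_transform))
    if (length(v) != 6) stop("chromatic_transform must have 6 numbers")
    raw$chromatic_transform <- affine2d(matrix(v[1:4], 2, 2, byrow = TRUE), v[5:6])
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, raw)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_frames, "frames @", x$frame_interval * 1000,
      "ms;", x$field_size_um, "um field;", x$complex_density,
      "complexes/um^2\n")
  on <- x$complex_mix[x$complex_mix > 0]
  cat("  mix:", paste(sprintf("%s=%.2f", names(on), on), collapse = ", "),
      "| labelling:", x$label_scheme, "| seed:", x$seed, "\n")
  invisible(x)
}
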