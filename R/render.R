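# Camera rendering: turn localizations into 16-bit TIRF-like frames with an
# integrated Gaussian PSF, Poisson photon noise and Gaussian read noise.

# integrated Gaussian weight of one emitter over a pixel grid window;
# pixel (row i, col j), 0-based, covers x in [j*px, (j+1)*px], y likewise.
.psf_window <- function(x_nm, y_nm, psf_sigma, pixel_size, n_rows, n_cols,
                        half_width) {
  jc <- floor(x_nm / pixel_size)
  ic <- floor(y_nm / pixel_size)
  j0 <- max(0, jc - half_width); j1 <- min(n_cols - 1, jc + half_width)
  i0 <- max(0, ic - half_width); i1 <- min(n_rows - 1, ic + half_width)
  if (j0 > j1 || i0 > i1) return(NULL)
  xe <- (j0:(j1 + 1)) * pixel_size
  ye <- (i0:(i1 + 1)) * pixel_size
  fx <- diff(pnorm(xe, mean = x_nm, sd = psf_sigma))
  fy <- diff(pnorm(ye, mean = y_nm, sd = psf_sigma))
  list(i = i0:i1, j = j0:j1, w = outer(fy, fx))
}

#' Render localizations as a synthetic camera movie
#'
#' Each emitter is rendered as a pixel-integrated 2D Gaussian of standard
#' deviation `psf_sigma`, its `intensity` interpreted as the expected photon
#' count for the frame. Per-pixel counts are Poisson draws of expected
#' photons (emitters + uniform background) scaled by `camera_gain`, plus
#' Gaussian read noise, rounded and clamped to the 16-bit range. Emitters
#' outside the field of view are silently clipped.
#'
#' @param locs A localization table for one channel (positions in that
#'   channel's camera frame).
#' @param config A [sim_config()] providing `psf_sigma`, `pixel_size`,
#'   `camera_gain`, `read_noise`, `background_photons`, `field_size_um`,
#'   `n_frames` and `seed`.
#' @param channel Which channel's rows of `locs` to render.
#' @return A `frame_stack` (list of integer matrices) with `pixel_size`
#'   attribute.
#' @export
render_movie <- function(locs, config, channel = "A") {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "render", match(channel, c("A", "B"))))
  px <- config$pixel_size
  n_px <- ceiling(config$field_size_um * 1000 / px)
  hw <- ceiling(5 * config$psf_sigma / px)
  locs <- locs[locs$channel == channel, , drop = FALSE]

  frames <- vector("list", config$n_frames)
  for (t in seq_len(config$n_frames)) {
    expected <- matrix(config$background_photons, n_px, n_px)
    rows <- which(locs$frame == t - 1L)
    for (r in rows) {
      w <- .psf_window(locs$x_nm[r], locs$y_nm[r], config$psf_sigma, px,
                       n_px, n_px, hw)
      if (is.null(w)) next
      expected[w$i + 1L, w$j + 1L] <-
        expected[w$i + 1L, w$j + 1L] + locs$intensity[r] * w$w
    }
    counts <- rpois(length(expected), expected) * config$camera_gain
    if (config$read_noise > 0)
      counts <- counts + rnorm(length(counts), 0, config$read_noise)
    m <- matrix(as.integer(pmin(pmax(round(counts), 0), 65535)), n_px, n_px)
    frames[[t]] <- m
  }
  structure(frames, class = "frame_stack", pixel_size = px,
            n_frames = length(frames))
}
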