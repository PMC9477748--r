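# Diffusion analysis: time-averaged mean squared displacement, diffusion
# constants by weighted linear regression, mobile/immobile fractions, and
# intensity-based higher-order-complex quantification.

#' Time-averaged MSD of one trajectory
#'
#' For each lag tau, the mean of squared displacements over all observed
#' frame pairs separated by exactly tau frames; pairs spanning gap frames
#' do not exist and contribute nothing.
#'
#' @param traj Data frame of one trajectory (`frame`, `x_nm`, `y_nm`).
#' @param max_lag Largest lag to evaluate (default: lifetime - 1).
#' @return A data frame `lag`, `msd_nm2`, `n_pairs` (lags with no pairs are
#'   dropped).
#' @export
compute_msd <- function(traj, max_lag = NULL) {
  if (nrow(traj) < 2)
    stop("MSD needs at least 2 observed frames")
  f <- traj$frame
  if (is.null(max_lag)) max_lag <- max(f) - min(f)
  idx <- order(f)
  f <- f[idx]
  x <- traj$x_nm[idx]
  y <- traj$y_nm[idx]
  n <- length(f)
  dmat <- outer(f, f, "-")
  out <- lapply(seq_len(max_lag), function(tau) {
    pairs <- which(dmat == tau, arr.ind = TRUE)   # [later, earlier]
    if (nrow(pairs) == 0) return(NULL)
    sq <- (x[pairs[, 1]] - x[pairs[, 2]])^2 + (y[pairs[, 1]] - y[pairs[, 2]])^2
    data.frame(lag = tau, msd_nm2 = mean(sq), n_pairs = nrow(pairs))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(lag = integer(), msd_nm2 = numeric(),
                                      n_pairs = integer())
  out
}

#' Pool MSD curves over trajectories
#'
#' Pair-count-weighted pooling: the pooled MSD at each lag is the mean over
#' all displacement pairs of all trajectories.
#'
#' @param trajs A trajectory table (multiple `trajectory_id`s).
#' @param min_lifetime Only trajectories with lifetime strictly greater
#'   than this enter the pool (default 10 frames).
#' @param max_lag Largest lag to evaluate.
#' @return A pooled MSD data frame (`lag`, `msd_nm2`, `n_pairs`).
#' @export
pooled_msd <- function(trajs, min_lifetime = 10, max_lag = 10) {
  if (nrow(trajs) == 0)
    return(data.frame(lag = integer(), msd_nm2 = numeric(),
                      n_pairs = integer()))
  by_id <- split(trajs, trajs$trajectory_id)
  curves <- lapply(by_id, function(tr) {
    if (nrow(tr) < 2) return(NULL)
    if (max(tr$frame) - min(tr$frame) + 1 <= min_lifetime) return(NULL)
    compute_msd(tr, max_lag = max_lag)
  })
  curves <- do.call(rbind, curves[!vapply(curves, is.null, logical(1))])
  if (is.null(curves) || nrow(curves) == 0)
    return(data.frame(lag = integer(), msd_nm2 = numeric(),
                      n_pairs = integer()))
  agg <- lapply(split(curves, curves$lag), function(d)
    data.frame(lag = d$lag[1],
               msd_nm2 = sum(d$msd_nm2 * d$n_pairs) / sum(d$n_pairs),
               n_pairs = sum(d$n_pairs)))
  res <- do.call(rbind, agg)
  res <- res[order(res$lag), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Fit a diffusion constant to an MSD curve
#'
#' Weighted linear regression of
#' \eqn{MSD(\tau) = 4 D \tau \Delta t + 4 \sigma^2}: the slope gives the
#' diffusion constant, the intercept the localization error. Weights are
#' the pair counts. Short lags (default 1-5) minimize confinement and
#' statistical bias. A negative slope is truncated to D = 0 and flagged; a
#' negative intercept is floored at sigma = 0.
#'
#' @param curve An MSD curve (`lag`, `msd_nm2`, `n_pairs`).
#' @param fit_lags Lags to use (default `1:5`); at least two must be
#'   present in the curve.
#' @param frame_interval Frame interval (s).
#' @return A list: `D_um2s`, `loc_error_sigma_hat_nm`, `fit_lags`,
#'   `r_squared`, `negative_slope` flag.
#' @export
fit_diffusion <- function(curve, fit_lags = 1:5, frame_interval = 0.032) {
  stopifnot(frame_interval > 0)
  d <- curve[curve$lag %in% fit_lags, , drop = FALSE]
  if (nrow(d) < 2)
    stop("fit needs >= 2 of the requested lags present in the MSD curve")
  t_s <- d$lag * frame_interval
  msd_um2 <- d$msd_nm2 * 1e-6
  fit <- lm(msd_um2 ~ t_s, weights = d$n_pairs)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  r2 <- suppressWarnings(summary(fit)$r.squared)   # exact lines are fine
  D <- slope / 4
  negative <- D < 0
  if (negative) {
    warning("negative MSD slope; diffusion constant truncated at 0")
    D <- 0
  }
  sigma_nm <- sqrt(max(intercept, 0) / 4) * 1000
  list(D_um2s = D, loc_error_sigma_hat_nm = sigma_nm,
       fit_lags = d$lag, r_squared = r2, negative_slope = negative)
}

#' Per-trajectory diffusion constants from lags 1-2
#'
#' Localization error cancels in the lag-1 to lag-2 difference:
#' \eqn{D = (MSD(2) - MSD(1)) / (4 \Delta t)}.
#'
#' @param trajs A trajectory table.
#' @param frame_interval Frame interval (s).
#' @return Data frame `trajectory_id`, `D_um2s` (NA when a lag is missing).
#' @export
per_trajectory_D <- function(trajs, frame_interval = 0.032) {
  by_id <- split(trajs, trajs$trajectory_id)
  out <- lapply(by_id, function(tr) {
    id <- tr$trajectory_id[1]
    if (nrow(tr) < 3)
      return(data.frame(trajectory_id = id, D_um2s = NA_real_))
    cv <- compute_msd(tr, max_lag = 2)
    if (!all(1:2 %in% cv$lag))
      return(data.frame(trajectory_id = id, D_um2s = NA_real_))
    msd1 <- cv$msd_nm2[cv$lag == 1] * 1e-6
    msd2 <- cv$msd_nm2[cv$lag == 2] * 1e-6
    data.frame(trajectory_id = id,
               D_um2s = (msd2 - msd1) / (4 * frame_interval))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Immobile fraction from per-trajectory diffusion constants
#'
#' @param trajs A trajectory table.
#' @param frame_interval Frame interval (s).
#' @param d_immobile_threshold Trajectories with per-trajectory D below
#'   this (um^2/s, default 0.01) count as immobile.
#' @param min_lifetime Only trajectories with lifetime strictly greater
#'   than this are classified (default 10).
#' @return A list: `immobile_fraction`, `D` (per-trajectory table),
#'   `n_classified`.
#' @export
mobility_fractions <- function(trajs, frame_interval = 0.032,
                               d_immobile_threshold = 0.01,
                               min_lifetime = 10) {
  st <- trajectory_stats(trajs)
  keep <- st$trajectory_id[st$lifetime > min_lifetime]
  sub <- trajs[trajs$trajectory_id %in% keep, , drop = FALSE]
  if (nrow(sub) == 0)
    return(list(immobile_fraction = NA_real_,
                D = data.frame(trajectory_id = integer(), D_um2s = numeric()),
                n_classified = 0L))
  dtab <- per_trajectory_D(sub, frame_interval)
  ok <- !is.na(dtab$D_um2s)
  list(immobile_fraction = mean(dtab$D_um2s[ok] < d_immobile_threshold),
       D = dtab, n_classified = sum(ok))
}

#' Monomer reference intensity of one channel
#'
#' Median per-trajectory mean intensity of mobile trajectories that never
#' enter a co-trajectory — the single-fluorophore brightness yardstick of
#' this cell and channel, robust to cell-to-cell illumination differences.
#'
#' @param mobile_trajs Mobile trajectory table of the channel.
#' @param colocalized_ids Trajectory ids that appear in any co-trajectory.
#' @return The reference intensity, or `NA` when no non-co-localized
#'   trajectory is available.
#' @export
monomer_reference_intensity <- function(mobile_trajs, colocalized_ids) {
  st <- trajectory_stats(mobile_trajs)
  ref <- st$mean_intensity[!(st$trajectory_id %in% colocalized_ids)]
  if (length(ref) == 0) return(NA_real_)
  median(ref)
}

#' Emission duty cycle of a channel
#'
#' Median fraction of observed frames within the lifetime of mobile,
#' non-co-localized trajectories. Blinking and missed detections make a
#' multi-fluorophore complex dimmer on average than multiplicity times the
#' monomer reference (each extra member contributes only while it emits,
#' whereas a monomer localization is by construction conditioned on
#' emission), so multiplicities are corrected by this observable duty
#' cycle. Clamped to `[0.5, 1]`; 1 means no blinking observed.
#'
#' @param mobile_trajs Mobile trajectory table of the channel.
#' @param colocalized_ids Trajectory ids that appear in any co-trajectory.
#' @return The duty cycle in `[0.5, 1]`, or `NA` when no reference
#'   trajectory is available.
#' @export
emission_duty <- function(mobile_trajs, colocalized_ids) {
  st <- trajectory_stats(mobile_trajs)
  st <- st[!(st$trajectory_id %in% colocalized_ids), , drop = FALSE]
  if (nrow(st) == 0) return(NA_real_)
  min(max(median(st$n_obs / st$lifetime), 0.5), 1)
}

#' Fraction of co-diffusing complexes that are higher-order
#'
#' Each dimer-called co-trajectory's per-channel multiplicity is its
#' initial (first matched frame) background-subtracted intensity divided by
#' the channel's monomer reference and by the channel's emission duty
#' cycle, rounded to the nearest integer; a complex is higher-order when
#' the multiplicity is 2 or more in either channel. The initial intensity
#' is used, as in subunit-counting practice, because blinking and bleaching
#' erode a complex's observable brightness over the movie and would bias
#' time-averaged multiplicities low; the optional duty-cycle correction
#' ([emission_duty()]) additionally compensates average dimming from
#' missed detections.
#'
#' @param dimer_calls Output of [call_dimers()], dimer rows only or mixed
#'   (non-dimers are ignored).
#' @param ref_a,ref_b Monomer reference intensities per channel.
#' @param duty_a,duty_b Emission duty cycles per channel (default 1: no
#'   correction).
#' @return A list: `oligomer_fraction` (NA when there are no dimers or no
#'   reference), `multiplicity_a`, `multiplicity_b` per dimer.
#' @export
oligomer_fraction <- function(dimer_calls, ref_a, ref_b,
                              duty_a = 1, duty_b = 1) {
  dimers <- dimer_calls[dimer_calls$is_dimer, , drop = FALSE]
  if (nrow(dimers) == 0 || is.na(ref_a) || is.na(ref_b) ||
      ref_a <= 0 || ref_b <= 0)
    return(list(oligomer_fraction = NA_real_,
                multiplicity_a = integer(), multiplicity_b = integer()))
  if (is.na(duty_a)) duty_a <- 1
  if (is.na(duty_b)) duty_b <- 1
  int_a <- if ("a_intensity_initial" %in% names(dimers))
    dimers$a_intensity_initial else dimers$a_intensity
  int_b <- if ("b_intensity_initial" %in% names(dimers))
    dimers$b_intensity_initial else dimers$b_intensity
  mult_a <- round(int_a / (ref_a * duty_a))
  mult_b <- round(int_b / (ref_b * duty_b))
  list(oligomer_fraction = mean(mult_a >= 2 | mult_b >= 2),
       multiplicity_a = as.integer(mult_a),
       multiplicity_b = as.integer(mult_b))
}
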