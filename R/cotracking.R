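# Two-colour co-tracking: frame-by-frame co-localization within a cutoff
# radius, linking of co-localized emitters into co-trajectories, dimer
# calling by co-diffusion persistence, and per-cell relative dimerization
# levels.

#' Dimer-calling parameters
#'
#' Defaults are the acquisition-matched constants: a 100 nm co-localization
#' cutoff and a 10-frame minimum co-diffusion persistence for a dimer call.
#'
#' @param cutoff_radius Co-localization cutoff (nm, default 100).
#' @param min_codiffusion_frames Minimum matched frames for a dimer call
#'   (default 10).
#' @param cotrack_max_gap Gap tolerance when linking co-localized pairs
#'   across frames (frames, default 1).
#' @param max_disp Maximum frame-to-frame displacement of a co-localized
#'   pair's midpoint (nm, default 500).
#' @return A list of class `dimer_params`.
#' @export
dimer_params <- function(cutoff_radius = 100, min_codiffusion_frames = 10,
                         cotrack_max_gap = 1, max_disp = 500) {
  stopifnot(cutoff_radius > 0, min_codiffusion_frames >= 1,
            cotrack_max_gap >= 0, max_disp > 0)
  structure(list(cutoff_radius = cutoff_radius,
                 min_codiffusion_frames = as.integer(min_codiffusion_frames),
                 cotrack_max_gap = as.integer(cotrack_max_gap),
                 max_disp = max_disp),
            class = "dimer_params")
}

#' Co-localize the two channels in one frame
#'
#' One-to-one matching minimizing total squared separation among pairs
#' within the cutoff radius (gated assignment on the thresholded distance
#' matrix). Both inputs must already be registered into the channel-A
#' coordinate frame.
#'
#' @param locs_a,locs_b Localization rows of one frame (columns `x_nm`,
#'   `y_nm`, `intensity`; a `trajectory_id` column is carried through when
#'   present).
#' @param cutoff Co-localization cutoff radius (nm).
#' @return A data frame of matches: indices `a_idx`, `b_idx` into the
#'   inputs, `separation_nm`, midpoint `x_nm`, `y_nm`, `a_intensity`,
#'   `b_intensity`, and `a_traj`/`b_traj` ids (NA when absent).
#' @export
colocalize_frame <- function(locs_a, locs_b, cutoff = 100) {
  stopifnot(cutoff > 0)
  empty <- data.frame(a_idx = integer(), b_idx = integer(),
                      separation_nm = numeric(), x_nm = numeric(),
                      y_nm = numeric(), a_intensity = numeric(),
                      b_intensity = numeric(), a_traj = integer(),
                      b_traj = integer())
  if (nrow(locs_a) == 0 || nrow(locs_b) == 0) return(empty)
  m <- .assign_points(locs_a$x_nm, locs_a$y_nm, locs_b$x_nm, locs_b$y_nm,
                      cutoff^2)
  a_idx <- which(m > 0)
  if (length(a_idx) == 0) return(empty)
  b_idx <- m[a_idx]
  get_traj <- function(tab, idx)
    if ("trajectory_id" %in% names(tab)) tab$trajectory_id[idx] else
      rep(NA_integer_, length(idx))
  data.frame(
    a_idx = a_idx, b_idx = b_idx,
    separation_nm = sqrt((locs_a$x_nm[a_idx] - locs_b$x_nm[b_idx])^2 +
                           (locs_a$y_nm[a_idx] - locs_b$y_nm[b_idx])^2),
    x_nm = (locs_a$x_nm[a_idx] + locs_b$x_nm[b_idx]) / 2,
    y_nm = (locs_a$y_nm[a_idx] + locs_b$y_nm[b_idx]) / 2,
    a_intensity = locs_a$intensity[a_idx],
    b_intensity = locs_b$intensity[b_idx],
    a_traj = get_traj(locs_a, a_idx), b_traj = get_traj(locs_b, b_idx))
}

#' Build co-trajectories from per-frame matches
#'
#' Match midpoints are linked across frames with the same assignment linker
#' used for single channels (`max_disp`, `cotrack_max_gap`). `n_matched`
#' counts matched frames only — gap frames do not count towards the
#' co-diffusion persistence.
#'
#' @param tracks_a,tracks_b Registered, mobility-filtered trajectory tables
#'   for channels A and B.
#' @param params A [dimer_params()].
#' @return A co-trajectory table: `cotraj_id`, `frame`, midpoint `x_nm`,
#'   `y_nm`, `separation_nm`, `a_intensity`, `b_intensity`, `a_traj`,
#'   `b_traj`.
#' @export
build_cotrajectories <- function(tracks_a, tracks_b, params = dimer_params()) {
  stopifnot(inherits(params, "dimer_params"))
  empty <- data.frame(cotraj_id = integer(), frame = integer(),
                      x_nm = numeric(), y_nm = numeric(),
                      separation_nm = numeric(), a_intensity = numeric(),
                      b_intensity = numeric(), a_traj = integer(),
                      b_traj = integer())
  if (nrow(tracks_a) == 0 || nrow(tracks_b) == 0) return(empty)
  frames <- sort(intersect(unique(tracks_a$frame), unique(tracks_b$frame)))
  matches <- list()
  a_by_f <- split(tracks_a, tracks_a$frame)
  b_by_f <- split(tracks_b, tracks_b$frame)
  for (f in frames) {
    mm <- colocalize_frame(a_by_f[[as.character(f)]],
                           b_by_f[[as.character(f)]], params$cutoff_radius)
    if (nrow(mm) > 0) {
      mm$frame <- f
      matches[[length(matches) + 1L]] <- mm
    }
  }
  if (length(matches) == 0) return(empty)
  stream <- do.call(rbind, matches)
  stream$channel <- "M"                       # midpoint pseudo-channel
  linked <- link_trajectories(stream, max_disp = params$max_disp,
                              max_gap = params$cotrack_max_gap)
  out <- data.frame(cotraj_id = linked$trajectory_id, frame = linked$frame,
                    x_nm = linked$x_nm, y_nm = linked$y_nm,
                    separation_nm = linked$separation_nm,
                    a_intensity = linked$a_intensity,
                    b_intensity = linked$b_intensity,
                    a_traj = linked$a_traj, b_traj = linked$b_traj)
  out[order(out$cotraj_id, out$frame), , drop = FALSE]
}

#' Call dimers from co-trajectories
#'
#' A co-trajectory whose emitters co-diffuse for at least
#' `min_codiffusion_frames` matched frames is called a dimer; shorter
#' co-localizations are treated as chance encounters.
#'
#' @param cotrajs A co-trajectory table from [build_cotrajectories()].
#' @param params A [dimer_params()].
#' @return One row per co-trajectory: `cotraj_id`, `n_matched`,
#'   `first_frame`, `last_frame`, `mean_separation_nm`, modal member ids
#'   `a_traj`, `b_traj`, mean intensities, and the `is_dimer` flag.
#' @export
call_dimers <- function(cotrajs, params = dimer_params()) {
  stopifnot(inherits(params, "dimer_params"))
  if (nrow(cotrajs) == 0)
    return(data.frame(cotraj_id = integer(), n_matched = integer(),
                      first_frame = integer(), last_frame = integer(),
                      mean_separation_nm = numeric(), a_traj = integer(),
                      b_traj = integer(), a_intensity = numeric(),
                      b_intensity = numeric(), is_dimer = logical()))
  modal <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_integer_)
    tb <- table(v)
    as.integer(names(tb)[which.max(tb)])
  }
  by_id <- split(seq_len(nrow(cotrajs)), cotrajs$cotraj_id)
  out <- lapply(by_id, function(r) {
    r <- r[order(cotrajs$frame[r])]
    data.frame(cotraj_id = cotrajs$cotraj_id[r[1]],
               n_matched = length(r),
               first_frame = min(cotrajs$frame[r]),
               last_frame = max(cotrajs$frame[r]),
               mean_separation_nm = mean(cotrajs$separation_nm[r]),
               a_traj = modal(cotrajs$a_traj[r]),
               b_traj = modal(cotrajs$b_traj[r]),
               a_intensity = mean(cotrajs$a_intensity[r]),
               b_intensity = mean(cotrajs$b_intensity[r]),
               # intensity before blinking/bleaching erode the complex
               a_intensity_initial = cotrajs$a_intensity[r[1]],
               b_intensity_initial = cotrajs$b_intensity[r[1]])
  })
  res <- do.call(rbind, out)
  res$is_dimer <- res$n_matched >= params$min_codiffusion_frames
  res <- res[order(res$cotraj_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Relative dimerization level of one cell
#'
#' The fraction of particles participating in dimer co-trajectories:
#' `n_dimers / min(n_tracks_a, n_tracks_b)`, where the track counts are
#' mobile trajectories with lifetime above the qualifying threshold. The
#' minimum is used as denominator so that a fully paired population gives
#' 1 under both the heterodimer and the two-colour homodimer labelling
#' schemes; raw counts are always reported alongside so other
#' normalizations can be recomputed.
#'
#' @param n_dimers Number of dimer-called co-trajectories.
#' @param n_tracks_a,n_tracks_b Qualifying track counts per channel.
#' @return The fraction in `[0, 1]`, or `NA` when either channel has no
#'   qualifying tracks (undefined, never reported as 0).
#' @export
relative_dimerization <- function(n_dimers, n_tracks_a, n_tracks_b) {
  stopifnot(n_dimers >= 0, n_tracks_a >= 0, n_tracks_b >= 0)
  denom <- min(n_tracks_a, n_tracks_b)
  if (denom == 0) return(NA_real_)
  n_dimers / denom
}
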