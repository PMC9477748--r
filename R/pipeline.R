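# End-to-end orchestration: simulate or ingest dual-channel data, register,
# track, filter, co-track, quantify, and compile the per-cell report.
# A single run seed is expanded into per-cell, per-stage substreams (see
# derive_seed) so cells are independent but the whole run is reproducible.

#' Analysis parameters of the co-tracking pipeline
#'
#' Acquisition-matched defaults: 100 nm co-localization cutoff, 10-frame
#' dimer persistence, 500 nm linking radius with 1-frame gap closing,
#' 75 nm radius-of-gyration immobile filter, qualifying-track lifetime
#' above 10 frames, MSD fit over lags 1-5.
#'
#' @param max_disp,max_gap Single-channel linking radius (nm) and gap
#'   tolerance (frames).
#' @param rg_threshold,rg_min_lifetime Immobile filter: radius of gyration
#'   (nm) and minimum lifetime (frames) for an immobile call.
#' @param dimer A [dimer_params()].
#' @param min_track_lifetime Tracks must live strictly longer than this
#'   (frames) to qualify for dimerization denominators and MSD pooling.
#' @param fit_lags MSD lags used in the diffusion fit.
#' @param d_immobile_threshold Per-trajectory D below this (um^2/s) counts
#'   as immobile.
#' @return A list of class `analysis_params`.
#' @export
analysis_params <- function(max_disp = 500, max_gap = 1, rg_threshold = 75,
                            rg_min_lifetime = 10, dimer = dimer_params(),
                            min_track_lifetime = 10, fit_lags = 1:5,
                            d_immobile_threshold = 0.01) {
  stopifnot(inherits(dimer, "dimer_params"))
  structure(list(max_disp = max_disp, max_gap = max_gap,
                 rg_threshold = rg_threshold,
                 rg_min_lifetime = rg_min_lifetime, dimer = dimer,
                 min_track_lifetime = min_track_lifetime,
                 fit_lags = fit_lags,
                 d_immobile_threshold = d_immobile_threshold),
            class = "analysis_params")
}

#' Simulate one cell's dual-channel localization data
#'
#' @param config A [sim_config()]; its `seed` fully determines the cell.
#' @param cell_id Cell identifier.
#' @return The [apply_observation_model()] output plus the `truth` and
#'   `config`.
#' @export
simulate_cell <- function(config, cell_id = "cell1") {
  truth <- simulate_receptor_truth(config)
  obs <- apply_observation_model(truth, config, cell_id = cell_id)
  c(obs, list(truth = truth, config = config))
}

#' Analyze one cell's registered dual-channel localizations
#'
#' Runs the per-cell chain: apply the B-to-A registration, link
#' trajectories per channel, filter immobile emitters, co-track within the
#' cutoff, call dimers, and quantify dimerization, diffusion, mobility and
#' higher-order fractions.
#'
#' @param locs_a,locs_b Localization tables for channels A and B (B in its
#'   own camera frame).
#' @param transform B-to-A [affine2d()] from [estimate_affine()]; identity
#'   to skip registration.
#' @param params An [analysis_params()].
#' @param frame_interval Frame interval (s).
#' @param cell_id,condition Identifiers for the result row.
#' @return A list: `result` (one-row per-cell data frame), plus the
#'   intermediate `tracks_a`, `tracks_b` (mobile), `immobile_a`,
#'   `immobile_b`, `cotrajectories` and `dimer_calls` for audit.
#' @export
analyze_cell <- function(locs_a, locs_b, transform = affine2d(),
                         params = analysis_params(),
                         frame_interval = 0.032,
                         cell_id = "cell1", condition = "default") {
  stopifnot(inherits(params, "analysis_params"))
  locs_b <- apply_affine(locs_b, transform)

  trk_a <- link_trajectories(locs_a, params$max_disp, params$max_gap)
  trk_b <- link_trajectories(locs_b, params$max_disp, params$max_gap)
  flt_a <- filter_immobile(trk_a, params$rg_threshold, params$rg_min_lifetime)
  flt_b <- filter_immobile(trk_b, params$rg_threshold, params$rg_min_lifetime)

  st_a <- trajectory_stats(flt_a$mobile)
  st_b <- trajectory_stats(flt_b$mobile)
  qual_a <- st_a[st_a$lifetime > params$min_track_lifetime, , drop = FALSE]
  qual_b <- st_b[st_b$lifetime > params$min_track_lifetime, , drop = FALSE]

  cotrajs <- build_cotrajectories(flt_a$mobile, flt_b$mobile, params$dimer)
  calls <- call_dimers(cotrajs, params$dimer)
  n_dimers <- sum(calls$is_dimer)
  rel_dim <- relative_dimerization(n_dimers, nrow(qual_a), nrow(qual_b))

  retag <- function(df, prefix, id_col = "trajectory_id") {
    df$trajectory_id <- if (nrow(df) == 0) character(0) else
      paste0(prefix, df[[id_col]])
    df
  }

  # diffusion: pooled over mobile tracks of both channels, lifetime > 10
  all_mobile <- rbind(retag(flt_a$mobile, "A")[, c("trajectory_id", "frame",
                                                   "x_nm", "y_nm")],
                      retag(flt_b$mobile, "B")[, c("trajectory_id", "frame",
                                                   "x_nm", "y_nm")])
  pm <- pooled_msd(all_mobile, min_lifetime = params$min_track_lifetime,
                   max_lag = max(params$fit_lags))
  D_free <- tryCatch(
    fit_diffusion(pm, params$fit_lags, frame_interval)$D_um2s,
    error = function(e) NA_real_)
  pm_co <- pooled_msd(retag(cotrajs, "M", "cotraj_id"),
                      min_lifetime = params$min_track_lifetime,
                      max_lag = max(params$fit_lags))
  D_cotrack <- tryCatch(
    fit_diffusion(pm_co, params$fit_lags, frame_interval)$D_um2s,
    error = function(e) NA_real_)

  # mobility over all tracks (pre-immobile-filter)
  all_tracks <- rbind(retag(trk_a, "A")[, c("trajectory_id", "frame",
                                            "x_nm", "y_nm", "intensity")],
                      retag(trk_b, "B")[, c("trajectory_id", "frame",
                                            "x_nm", "y_nm", "intensity")])
  mob <- mobility_fractions(all_tracks, frame_interval,
                            params$d_immobile_threshold,
                            params$min_track_lifetime)

  coloc_a <- unique(calls$a_traj[calls$is_dimer])
  coloc_b <- unique(calls$b_traj[calls$is_dimer])
  ref_a <- monomer_reference_intensity(flt_a$mobile, coloc_a)
  ref_b <- monomer_reference_intensity(flt_b$mobile, coloc_b)
  olig <- oligomer_fraction(calls, ref_a, ref_b,
                            emission_duty(flt_a$mobile, coloc_a),
                            emission_duty(flt_b$mobile, coloc_b))

  result <- data.frame(
    cell_id = cell_id, condition = condition,
    n_tracks_a = nrow(qual_a), n_tracks_b = nrow(qual_b),
    n_dimers = n_dimers, relative_dimerization = rel_dim,
    D_um2s = D_free, D_cotrack_um2s = D_cotrack,
    immobile_fraction = mob$immobile_fraction,
    oligomer_fraction = olig$oligomer_fraction,
    stringsAsFactors = FALSE)

  list(result = result, tracks_a = flt_a$mobile, tracks_b = flt_b$mobile,
       immobile_a = flt_a$immobile, immobile_b = flt_b$immobile,
       cotrajectories = cotrajs, dimer_calls = calls)
}

#' Simulate and analyze one cell
#'
#' Convenience wrapper: simulate a cell under `config`, estimate the
#' chromatic registration from a fiducial set generated with the same
#' transform, and analyze.
#'
#' @param config A [sim_config()].
#' @param params An [analysis_params()].
#' @param cell_id,condition Identifiers.
#' @param registration `"fiducial"` (estimate from 50 simulated markers
#'   with 3 nm noise), `"exact"` (use the inverse of the true chromatic
#'   transform), or an [affine2d()] to use directly.
#' @return As [analyze_cell()], plus `truth` and `identity`.
#' @export
simulate_and_analyze_cell <- function(config, params = analysis_params(),
                                      cell_id = "cell1",
                                      condition = "default",
                                      registration = "fiducial") {
  sim <- simulate_cell(config, cell_id)
  if (inherits(registration, "affine2d")) {
    tr <- registration
  } else if (identical(registration, "exact")) {
    tr <- invert_affine(config$chromatic_transform)
  } else {
    fid <- make_fiducial_set(config$chromatic_transform, n_markers = 50,
                             marker_noise_sigma = 3,
                             seed = derive_seed(config$seed, "register"))
    tr <- estimate_affine(fid$points_a, fid$points_b)$transform
  }
  res <- analyze_cell(sim$locs_a, sim$locs_b, tr, params,
                      config$frame_interval, cell_id, condition)
  c(res, list(truth = sim$truth, identity = sim$identity))
}

#' Run the full pipeline over simulated conditions
#'
#' For each condition, simulates `n_cells` cells (per-cell seeds derived
#' from the run seed), analyzes each, and compiles the per-condition report
#' with pairwise KS tests. When `out_dir` is given, all intermediates are
#' written: the registration transform (JSON), per-cell localization tables
#' and trajectories (CSV), the per-cell results table (CSV) and the report
#' (JSON). Rerunning with the same configuration and seed reproduces every
#' output exactly.
#'
#' @param conditions Named list; each element is a list with `config` (a
#'   [sim_config()]; its seed is overridden per cell) and optional
#'   `n_cells` (default 10).
#' @param params An [analysis_params()].
#' @param seed Run seed.
#' @param out_dir Output directory (created), or `NULL` to skip writing.
#' @param registration As in [simulate_and_analyze_cell()].
#' @return The `cotrack_report`, with the per-cell table in `$per_cell`.
#' @export
run_pipeline <- function(conditions, params = analysis_params(), seed = 1L,
                         out_dir = NULL, registration = "fiducial") {
  stopifnot(length(conditions) > 0, !is.null(names(conditions)))
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # one channel calibration per run, shared by all cells
  first_cfg <- conditions[[1]]$config
  if (inherits(registration, "affine2d")) {
    tr <- registration
  } else if (identical(registration, "exact")) {
    tr <- invert_affine(first_cfg$chromatic_transform)
  } else {
    fid <- make_fiducial_set(first_cfg$chromatic_transform, n_markers = 50,
                             marker_noise_sigma = 3,
                             seed = derive_seed(seed, "register"))
    tr <- estimate_affine(fid$points_a, fid$points_b)$transform
  }
  if (!is.null(out_dir))
    write_affine(tr, file.path(out_dir, "registration_transform.json"))

  rows <- list()
  for (cond in names(conditions)) {
    spec <- conditions[[cond]]
    n_cells <- if (is.null(spec$n_cells)) 10L else spec$n_cells
    cfg <- spec$config
    for (k in seq_len(n_cells)) {
      cell_cfg <- cfg
      cell_cfg$seed <- derive_seed(seed, paste0("cell-", cond), k)
      cell_id <- sprintf("%s_cell%02d", cond, k)
      sim <- simulate_cell(cell_cfg, cell_id)
      res <- tryCatch(
        analyze_cell(sim$locs_a, sim$locs_b, tr, params,
                     cell_cfg$frame_interval, cell_id, cond),
        error = function(e) stop("stage 'analyze' failed for cell ",
                                 cell_id, ": ", conditionMessage(e)))
      rows[[length(rows) + 1L]] <- res$result
      if (!is.null(out_dir)) {
        write_localizations(rbind(sim$locs_a, sim$locs_b),
                            file.path(out_dir,
                                      paste0(cell_id, "_localizations.csv")))
        trk <- rbind(res$tracks_a, res$tracks_b)
        write.csv(trk[, c("trajectory_id", "channel", "frame", "x_nm",
                          "y_nm", "intensity")],
                  file.path(out_dir, paste0(cell_id, "_trajectories.csv")),
                  row.names = FALSE)
        write.csv(res$cotrajectories,
                  file.path(out_dir, paste0(cell_id, "_cotrajectories.csv")),
                  row.names = FALSE)
      }
    }
  }
  cell_results <- do.call(rbind, rows)
  report <- compile_report(cell_results)
  report$seed <- seed
  if (!is.null(out_dir)) {
    write.csv(cell_results, file.path(out_dir, "per_cell_results.csv"),
              row.names = FALSE)
    write_report(report, file.path(out_dir, "report.json"))
  }
  report
}

#' Parameter-recovery experiment over a ground-truth grid
#'
#' For each ground-truth heterodimer proportion, simulates `n_cells` cells
#' and records the estimated relative dimerization against the truth, with
#' Monte-Carlo spread.
#'
#' @param dimer_proportions Ground-truth heterodimer proportions to
#'   simulate.
#' @param n_cells Cells per grid point.
#' @param base_config Template [sim_config()]; its `complex_mix` is
#'   replaced at each grid point by a heterodimer/monomer mixture with the
#'   monomer remainder split equally between the two receptors.
#' @param params An [analysis_params()].
#' @param seed Run seed.
#' @return A data frame: `truth`, `mean_estimate`, `sd_estimate`,
#'   `n_cells`, plus the per-cell estimates as the `cells` attribute.
#' @export
run_recovery_experiment <- function(dimer_proportions, n_cells = 10,
                                    base_config = sim_config(),
                                    params = analysis_params(), seed = 1L) {
  stopifnot(length(dimer_proportions) > 0,
            all(dimer_proportions >= 0 & dimer_proportions <= 1))
  out <- list()
  cells <- list()
  for (gi in seq_along(dimer_proportions)) {
    p <- dimer_proportions[gi]
    cfg <- base_config
    cfg$complex_mix <- .mix_with_heterodimer(p)
    est <- numeric(n_cells)
    for (k in seq_len(n_cells)) {
      cell_cfg <- cfg
      cell_cfg$seed <- derive_seed(seed, paste0("recover-", gi), k)
      res <- simulate_and_analyze_cell(cell_cfg, params,
                                       sprintf("p%03d_cell%02d",
                                               round(1000 * p), k),
                                       condition = sprintf("p=%.2f", p))
      est[k] <- res$result$relative_dimerization
    }
    cells[[gi]] <- data.frame(truth = p, estimate = est)
    out[[gi]] <- data.frame(truth = p,
                            mean_estimate = mean(est, na.rm = TRUE),
                            sd_estimate = sd(est, na.rm = TRUE),
                            n_cells = n_cells)
  }
  res <- do.call(rbind, out)
  attr(res, "cells") <- do.call(rbind, cells)
  res
}

#' Analyze an experiment from localization tables on disk
#'
#' Tables mode of the pipeline: instead of simulating, each cell's
#' dual-channel localizations are read from CSV (channel B in its own
#' camera frame), registered with the supplied transform, and pushed
#' through the same per-cell chain as [run_pipeline()].
#'
#' @param cells Data frame with one row per cell: `cell_id`, `condition`,
#'   `path_a`, `path_b` (localization CSVs for channels A and B).
#' @param transform The B-to-A [affine2d()] from fiducial calibration.
#' @param params An [analysis_params()].
#' @param frame_interval Frame interval (s).
#' @param out_dir Optional output directory for the per-cell table and
#'   report.
#' @return The `cotrack_report`.
#' @export
run_pipeline_tables <- function(cells, transform, params = analysis_params(),
                                frame_interval = 0.032, out_dir = NULL) {
  stopifnot(is.data.frame(cells),
            all(c("cell_id", "condition", "path_a", "path_b") %in%
                  names(cells)))
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    res <- tryCatch(
      analyze_cell(read_localizations(cells$path_a[k]),
                   read_localizations(cells$path_b[k]),
                   transform, params, frame_interval,
                   cells$cell_id[k], cells$condition[k]),
      error = function(e) stop("stage 'analyze' failed for cell ",
                               cells$cell_id[k], ": ",
                               conditionMessage(e)))
    res$result
  })
  cell_results <- do.call(rbind, rows)
  report <- compile_report(cell_results)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(cell_results, file.path(out_dir, "per_cell_results.csv"),
              row.names = FALSE)
    write_report(report, file.path(out_dir, "report.json"))
  }
  report
}

#' Higher-order-complex recovery experiment
#'
#' Simulates a two-colour-labelled single-receptor population (split
#' labelling) containing hexameric arrays alongside homodimers and
#' monomers, runs the full co-tracking chain, and compares the
#' intensity-based higher-order fraction against the per-cell ground truth
#' read off the simulator's identity map: the fraction of dimer-called
#' co-trajectories whose underlying complex had two or more members
#' emitting in either channel at the frame where the co-trajectory begins.
#' Blinking and photobleaching genuinely reduce the observable
#' stoichiometry of a complex over the movie — a dark fluorophore carries
#' no intensity information — so the recoverable truth is defined at the
#' co-trajectory's start, matching the information available to the
#' intensity estimator.
#'
#' @param n_cells Number of cells.
#' @param base_config Template [sim_config()]; `label_scheme` is forced to
#'   `"split"`. The default mix is 10 % hexamers among complexes with
#'   homodimers and monomers of one receptor.
#' @param params An [analysis_params()].
#' @param seed Run seed.
#' @return Data frame with one row per cell: `cell`, `truth_fraction`,
#'   `estimated_fraction`, `n_dimers`.
#' @export
oligomer_recovery_experiment <- function(n_cells = 10,
                                         base_config = sim_config(
                                           complex_mix = c(monomer_B = 0.5,
                                                           homodimer_BB = 0.4,
                                                           hexamer_B6 = 0.1)),
                                         params = analysis_params(),
                                         seed = 1L) {
  out <- list()
  for (k in seq_len(n_cells)) {
    cfg <- base_config
    cfg$label_scheme <- "split"
    cfg$seed <- derive_seed(seed, "oligomer", k)
    sim <- simulate_cell(cfg, sprintf("olig_cell%02d", k))

    # thread the true complex identity through the analysis for the oracle
    ids <- sim$identity
    locs_a <- sim$locs_a
    locs_a$complex_id <- ids$complex_id[ids$channel == "A"]
    locs_b <- sim$locs_b
    locs_b$complex_id <- ids$complex_id[ids$channel == "B"]

    fid <- make_fiducial_set(cfg$chromatic_transform, n_markers = 50,
                             marker_noise_sigma = 3,
                             seed = derive_seed(cfg$seed, "register"))
    tr <- estimate_affine(fid$points_a, fid$points_b)$transform
    locs_b <- apply_affine(locs_b, tr)

    trk_a <- link_trajectories(locs_a, params$max_disp, params$max_gap)
    trk_b <- link_trajectories(locs_b, params$max_disp, params$max_gap)
    flt_a <- filter_immobile(trk_a, params$rg_threshold,
                             params$rg_min_lifetime)
    flt_b <- filter_immobile(trk_b, params$rg_threshold,
                             params$rg_min_lifetime)
    cotrajs <- build_cotrajectories(flt_a$mobile, flt_b$mobile, params$dimer)
    calls <- call_dimers(cotrajs, params$dimer)
    dimers <- calls[calls$is_dimer, , drop = FALSE]

    ref_a <- monomer_reference_intensity(flt_a$mobile, dimers$a_traj)
    ref_b <- monomer_reference_intensity(flt_b$mobile, dimers$b_traj)
    est <- oligomer_fraction(calls, ref_a, ref_b,
                             emission_duty(flt_a$mobile, dimers$a_traj),
                             emission_duty(flt_b$mobile, dimers$b_traj)
                             )$oligomer_fraction

    truth <- NA_real_
    if (nrow(dimers) > 0) {
      modal_complex <- function(traj_ids, trk) {
        vapply(traj_ids, function(id) {
          v <- trk$complex_id[trk$trajectory_id == id]
          v <- v[!is.na(v)]
          if (length(v) == 0) return(NA_integer_)
          tb <- table(v)
          as.integer(names(tb)[which.max(tb)])
        }, integer(1))
      }
      cid <- modal_complex(dimers$a_traj, flt_a$mobile)
      P <- sim$truth$particles
      hi <- vapply(seq_len(nrow(dimers)), function(k) {
        ci <- cid[k]
        if (is.na(ci)) return(NA)
        t0 <- dimers$first_frame[k] + 1L            # 1-based column
        members <- which(P$complex_id == ci)
        act <- members[sim$emitting[members, t0]]
        sum(P$channel[act] == "A") >= 2 || sum(P$channel[act] == "B") >= 2
      }, logical(1))
      truth <- mean(hi, na.rm = TRUE)
    }
    out[[k]] <- data.frame(cell = k, truth_fraction = truth,
                           estimated_fraction = est,
                           n_dimers = nrow(dimers))
  }
  do.call(rbind, out)
}

# heterodimer proportion p among complexes, remainder split between the two
# free monomers; expanded over all complex types for direct assignment into
# an existing config
.mix_with_heterodimer <- function(p) {
  full <- setNames(rep(0, length(COMPLEX_TYPES)), COMPLEX_TYPES)
  full["monomer_A"] <- (1 - p) / 2
  full["monomer_B"] <- (1 - p) / 2
  full["heterodimer_AB"] <- p
  full
}
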