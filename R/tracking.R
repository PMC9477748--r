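# Trajectory building: frame-to-frame linking by minimum-total-squared-
# displacement assignment with a hard search radius, post-hoc gap closing,
# and immobile-emitter filtering by trajectory radius of gyration.

# gated one-to-one assignment between two point sets; returns for each row
# of (x1, y1) the matched index into (x2, y2) or 0. Cost is squared
# distance; pairs farther than sqrt(gate_cost) apart can never link.
.assign_points <- function(x1, y1, x2, y2, gate_cost,
                           dummy_cost = gate_cost) {
  n <- length(x1); m <- length(x2)
  if (n == 0 || m == 0) return(integer(n))
  cost <- outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2
  gated_assignment_cpp(cost, gate_cost, dummy_cost)$match
}

#' Link localizations into trajectories
#'
#' For each consecutive frame pair, open track ends are matched to the next
#' frame's localizations by the one-to-one assignment minimizing total
#' squared displacement, with links forbidden beyond `max_disp`. Track ends
#' are then joined to later track starts when the frame gap is at most
#' `max_gap` and the displacement at most `max_disp * sqrt(gap + 1)`
#' (again by minimum-cost one-to-one assignment). Every localization
#' belongs to at most one trajectory.
#'
#' @param table A single-channel localization table (columns `frame`,
#'   `x_nm`, `y_nm`; other columns are carried along).
#' @param max_disp Maximum frame-to-frame displacement (nm).
#' @param max_gap Maximum number of missing frames a trajectory may bridge.
#' @return The table with a `trajectory_id` column, ordered by trajectory
#'   then frame. Trajectory ids are dense integers, deterministic for a
#'   given input.
#' @export
link_trajectories <- function(table, max_disp = 500, max_gap = 1) {
  stopifnot(max_disp > 0, max_gap >= 0)
  if (nrow(table) == 0) {
    table$trajectory_id <- integer(0)
    return(table)
  }
  if (length(unique(table$channel)) > 1)
    stop("link_trajectories expects a single channel")
  tab <- table[order(table$frame), , drop = FALSE]
  gate <- max_disp^2

  track_of <- integer(nrow(tab))          # provisional track id per row
  frames <- sort(unique(tab$frame))
  idx_by_frame <- split(seq_len(nrow(tab)), tab$frame)
  next_id <- 0L
  # rows of the currently open track ends, keyed by track id
  first_f <- frames[1]
  open_rows <- idx_by_frame[[as.character(first_f)]]
  track_of[open_rows] <- seq_along(open_rows)
  next_id <- length(open_rows)
  prev_frame <- first_f

  for (f in frames[-1]) {
    cur <- idx_by_frame[[as.character(f)]]
    matched <- integer(length(cur))
    if (f == prev_frame + 1) {
      m <- .assign_points(tab$x_nm[open_rows], tab$y_nm[open_rows],
                          tab$x_nm[cur], tab$y_nm[cur], gate)
      for (k in seq_along(open_rows)) {
        if (m[k] > 0) {
          track_of[cur[m[k]]] <- track_of[open_rows[k]]
          matched[m[k]] <- 1L
        }
      }
    }
    new <- cur[matched == 0L]
    if (length(new) > 0) {
      track_of[new] <- next_id + seq_along(new)
      next_id <- next_id + length(new)
    }
    # open ends: rows at frame f (consecutive-frame linking only)
    open_rows <- cur
    prev_frame <- f
  }

  # gap closing: join track ends to later track starts
  if (max_gap > 0 && next_id > 1) {
    by_track <- split(seq_len(nrow(tab)), track_of)
    ids <- as.integer(names(by_track))
    end_row <- vapply(by_track, function(r) r[which.max(tab$frame[r])],
                      integer(1))
    start_row <- vapply(by_track, function(r) r[which.min(tab$frame[r])],
                        integer(1))
    end_f <- tab$frame[end_row]
    start_f <- tab$frame[start_row]
    # admissible (end, start) pairs
    gap <- outer(start_f, end_f, "-") - 1        # [start, end]
    d2 <- (outer(tab$x_nm[start_row], tab$x_nm[end_row], "-"))^2 +
      (outer(tab$y_nm[start_row], tab$y_nm[end_row], "-"))^2
    admissible <- gap >= 1 & gap <= max_gap &
      d2 <= gate * (gap + 1)
    if (any(admissible)) {
      cost <- d2
      cost[!admissible] <- Inf
      res <- gated_assignment_cpp(t(cost), gate * (max_gap + 1),
                                  gate * (max_gap + 1) + 1)
      m <- res$match                             # ends -> starts
      # merge: track whose start is matched inherits the earlier track's id
      parent <- seq_along(ids)
      for (k in seq_along(m)) {
        if (m[k] > 0) parent[m[k]] <- k          # start m[k] joins end k
      }
      resolve <- function(i) {
        while (parent[i] != i) i <- parent[i]
        i
      }
      root <- vapply(seq_along(ids), resolve, integer(1))
      map <- ids[root]
      names(map) <- as.character(ids)
      track_of <- map[as.character(track_of)]
    }
  }

  # dense, deterministic ids ordered by (first frame, x, y) of track start
  by_track <- split(seq_len(nrow(tab)), track_of)
  starts <- t(vapply(by_track, function(r) {
    r0 <- r[which.min(tab$frame[r])]
    c(tab$frame[r0], tab$x_nm[r0], tab$y_nm[r0])
  }, numeric(3)))
  ord <- order(starts[, 1], starts[, 2], starts[, 3])
  new_id <- integer(length(by_track))
  new_id[ord] <- seq_along(by_track)
  id_map <- setNames(new_id, names(by_track))
  tab$trajectory_id <- as.integer(id_map[as.character(track_of)])
  tab <- tab[order(tab$trajectory_id, tab$frame), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Per-trajectory summary statistics
#'
#' @param trajs A trajectory table from [link_trajectories()].
#' @return One row per trajectory: `trajectory_id`, `n_obs`, `first_frame`,
#'   `last_frame`, `lifetime` (frames from first to last, inclusive),
#'   `radius_gyration_nm`, `mean_intensity`.
#' @export
trajectory_stats <- function(trajs) {
  if (nrow(trajs) == 0)
    return(data.frame(trajectory_id = integer(), n_obs = integer(),
                      first_frame = integer(), last_frame = integer(),
                      lifetime = integer(), radius_gyration_nm = numeric(),
                      mean_intensity = numeric()))
  by_id <- split(seq_len(nrow(trajs)), trajs$trajectory_id)
  out <- lapply(by_id, function(r) {
    x <- trajs$x_nm[r]; y <- trajs$y_nm[r]; f <- trajs$frame[r]
    rg <- sqrt(mean((x - mean(x))^2 + (y - mean(y))^2))
    data.frame(trajectory_id = trajs$trajectory_id[r[1]],
               n_obs = length(r), first_frame = min(f), last_frame = max(f),
               lifetime = max(f) - min(f) + 1L,
               radius_gyration_nm = rg,
               mean_intensity = mean(trajs$intensity[r]))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$trajectory_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter immobile emitters by radius of gyration
#'
#' A trajectory observed for at least `min_lifetime` frames whose radius of
#' gyration is below `rg_threshold` is classified immobile and excluded
#' from co-tracking and diffusion analysis. Both partitions are returned
#' for audit. (Short trajectories cannot be reliably classified and are
#' kept in the mobile partition.)
#'
#' @param trajs A trajectory table from [link_trajectories()].
#' @param rg_threshold Radius-of-gyration threshold (nm; default 75).
#' @param min_lifetime Minimum lifetime for the immobile call (frames;
#'   default 10).
#' @return A list with `mobile` and `immobile` trajectory tables and the
#'   per-trajectory `stats` with an `immobile` flag.
#' @export
filter_immobile <- function(trajs, rg_threshold = 75, min_lifetime = 10) {
  stopifnot(rg_threshold > 0, min_lifetime > 0)
  st <- trajectory_stats(trajs)
  st$immobile <- st$lifetime >= min_lifetime &
    st$radius_gyration_nm < rg_threshold
  imm_ids <- st$trajectory_id[st$immobile]
  list(mobile = trajs[!(trajs$trajectory_id %in% imm_ids), , drop = FALSE],
       immobile = trajs[trajs$trajectory_id %in% imm_ids, , drop = FALSE],
       stats = st)
}
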