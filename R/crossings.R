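#' First-crossing events of one trajectory
#'
#' The event primitive of spatiotemporal survival analysis. The travelled
#' distance is tiled by incremental spatial thresholds (by default 20 steps
#' of 5\% of the total distance); for each threshold the FIRST sample whose
#' absolute position reaches it yields one event, stamped with the direction
#' of travel at that sample. A crossing toward the Match box (positive x) is
#' correct on Match trials and incorrect on non-Match trials, and vice
#' versa — segments are scored by direction alone, regardless of the trial's
#' ultimate outcome. Thresholds never reached yield no event. Detection is
#' sample-exact, with no sub-sample interpolation.
#'
#' @param t_ms,x_m Trajectory samples: strictly increasing times (ms) and
#'   signed positions (m, positive toward the Match box).
#' @param trial_type \code{"match"} or \code{"nonmatch"}.
#' @param grid An \code{\link{stsa_grid}}.
#' @param trial_id Optional id carried into the result.
#' @return data.frame with one row per crossed threshold: \code{trial_id},
#'   \code{threshold_index}, \code{threshold_m}, \code{t_ms}, \code{bin}
#'   (temporal bin of the event), \code{direction} (+1/-1), \code{correct}.
#' @examples
#' tr <- data.frame(t_ms = seq(0, 1000, by = 50),
#'                  x_m  = seq(0, 0.2, length.out = 21))
#' ev <- extract_crossings(tr$t_ms, tr$x_m, "match")
#' nrow(ev)  # 20 thresholds, all crossed
#' @export
extract_crossings <- function(t_ms, x_m, trial_type, grid = stsa_grid(),
                              trial_id = NA_character_) {
  stopifnot(inherits(grid, "stsa_grid"), length(t_ms) == length(x_m))
  if (!length(t_ms)) stop("empty trajectory")
  if (any(diff(t_ms) <= 0))
    stop("non-monotone timestamps in trajectory",
         if (!is.na(trial_id)) paste0(" of trial ", trial_id) else "")
  trial_type <- match.arg(trial_type, c("match", "nonmatch"))
  amax <- cummax(abs(x_m))
  idx <- vapply(grid$thresholds_m,
                function(thr) match(TRUE, amax >= thr), integer(1))
  crossed <- which(!is.na(idx))
  i <- idx[crossed]
  dir <- sign(x_m[i])
  data.frame(trial_id = rep(trial_id, length(crossed)),
             threshold_index = crossed,
             threshold_m = grid$thresholds_m[crossed],
             t_ms = t_ms[i],
             bin = as.integer(pmax(1, ceiling(t_ms[i] / grid$temporal$bin_ms))),
             direction = dir,
             correct = (dir > 0) == (trial_type == "match"),
             stringsAsFactors = FALSE)
}

#' Crossing events for a whole dataset
#'
#' Applies \code{\link{extract_crossings}} to every trial with a trajectory
#' and keeps, per trial, the information the hazard risk sets need: the
#' trial's condition labels and the temporal bin of its last recorded sample
#' (a trial stays at risk for an uncrossed threshold until its recording
#' ends). Trials are never trimmed at this stage.
#'
#' @param dataset An \code{\link{stsa_dataset}}.
#' @param grid An \code{\link{stsa_grid}}.
#' @return Object of class \code{"crossing_events"}: list with \code{events}
#'   (event rows joined with participant / n_back / trial_type),
#'   \code{trials} (one row per trajectory trial: ids, condition,
#'   \code{end_ms}, \code{end_bin}) and the grid.
#' @export
crossing_events <- function(dataset, grid = stsa_grid()) {
  stopifnot(inherits(dataset, "stsa_dataset"))
  traj_ids <- unique(dataset$trajectories$trial_id)
  if (!length(traj_ids)) stop("dataset has no trajectories")
  tr <- dataset$trials[match(traj_ids, dataset$trials$trial_id), , drop = FALSE]
  by_trial <- split(dataset$trajectories[c("t_ms", "x_m")],
                    dataset$trajectories$trial_id)[traj_ids]
  ev_list <- vector("list", length(traj_ids))
  end_ms <- numeric(length(traj_ids))
  for (i in seq_along(traj_ids)) {
    s <- by_trial[[i]]
    end_ms[i] <- max(s$t_ms)
    ev_list[[i]] <- extract_crossings(s$t_ms, s$x_m, tr$trial_type[i], grid,
                                      trial_id = traj_ids[i])
  }
  events <- do.call(rbind, c(ev_list, list(make.row.names = FALSE)))
  meta_idx <- match(events$trial_id, tr$trial_id)
  events$participant <- tr$participant[meta_idx]
  events$n_back <- tr$n_back[meta_idx]
  events$trial_type <- tr$trial_type[meta_idx]
  trials <- data.frame(trial_id = traj_ids,
                       participant = tr$participant,
                       n_back = tr$n_back,
                       trial_type = tr$trial_type,
                       end_ms = end_ms,
                       end_bin = as.integer(pmax(1, ceiling(end_ms / grid$temporal$bin_ms))))
  structure(list(events = events, trials = trials, grid = grid),
            class = "crossing_events")
}

#' @export
print.crossing_events <- function(x, ...) {
  cat(sprintf("Crossing events: %d events from %d trials (%d thresholds x %g ms bins)\n",
              nrow(x$events), nrow(x$trials), x$grid$n_spatial,
              x$grid$temporal$bin_ms))
  invisible(x)
}

#' Subset crossing events by condition
#'
#' @param events A \code{"crossing_events"} object.
#' @param ... Named condition values matched against the trial table, e.g.
#'   \code{n_back = 1, trial_type = "match"}.
#' @return A filtered \code{"crossing_events"} object.
#' @export
filter_events <- function(events, ...) {
  stopifnot(inherits(events, "crossing_events"))
  cond <- list(...)
  keep <- rep(TRUE, nrow(events$trials))
  for (nm in names(cond))
    keep <- keep & events$trials[[nm]] %in% cond[[nm]]
  ids <- events$trials$trial_id[keep]
  structure(list(events = events$events[events$events$trial_id %in% ids, ,
                                        drop = FALSE],
                 trials = events$trials[keep, , drop = FALSE],
                 grid = events$grid),
            class = "crossing_events")
}

.maps_dims <- function(events) {
  grid <- events$grid
  last <- max(c(events$events$bin, events$trials$end_bin,
                grid$temporal$display_bins))
  c(grid$n_spatial, last)
}

#' Spatiotemporal hazard and conditional-accuracy maps
#'
#' Per spatial threshold k and temporal bin t, the hazard
#' H(k, t) = events(k, t) / at-risk(k, t) is the conditional probability
#' that a trajectory first crosses threshold k in bin t given it has not
#' crossed it before; each spatial row is an independent discrete-time
#' hazard. A trial leaves row k's risk set at its first crossing of k, or at
#' its last recorded sample if it never crosses. CA(k, t) is the mean
#' directional correctness of the events in the cell, undefined (NA) where a
#' cell has no events. Computation runs to the last observed bin; the
#' display window only truncates plots.
#'
#' @param events A \code{"crossing_events"} object (typically filtered to one
#'   condition).
#' @return Object of class \code{"stsa_maps"}: list with matrices \code{H},
#'   \code{CA}, \code{n_events}, \code{n_at_risk} (rows = spatial thresholds
#'   in increasing order, cols = temporal bins), \code{n_trials}, the grid
#'   and \code{scale} (NA until \code{\link{scale_maps}}).
#' @export
stsa_maps <- function(events) {
  stopifnot(inherits(events, "crossing_events"))
  dims <- .maps_dims(events)
  K <- dims[1]; TT <- dims[2]
  n_events <- n_correct <- n_at_risk <- matrix(0L, K, TT)
  ev <- events$events
  end_bin <- events$trials$end_bin
  for (k in seq_len(K)) {
    evk <- ev[ev$threshold_index == k, , drop = FALSE]
    tab <- tabulate(evk$bin, nbins = TT)
    n_events[k, ] <- tab
    n_correct[k, ] <- tabulate(evk$bin[evk$correct], nbins = TT)
    # non-crossers stay at risk until their recording ends
    nc_end <- end_bin[!(events$trials$trial_id %in% evk$trial_id)]
    risk_ev <- rev(cumsum(rev(tab)))                       # crossers with bin >= t
    risk_nc <- rev(cumsum(rev(tabulate(nc_end, nbins = TT))))
    n_at_risk[k, ] <- risk_ev + risk_nc
  }
  H <- ifelse(n_at_risk > 0, n_events / n_at_risk, 0)
  CA <- ifelse(n_events > 0, n_correct / n_events, NA_real_)
  structure(list(H = H, CA = CA, n_events = n_events, n_at_risk = n_at_risk,
                 n_trials = nrow(events$trials), grid = events$grid,
                 scale = NA_real_),
            class = "stsa_maps")
}

#' Hazard part of the spatiotemporal maps
#'
#' @param events A \code{"crossing_events"} object.
#' @return Matrix H (spatial thresholds x temporal bins).
#' @export
stsa_hazard <- function(events) stsa_maps(events)$H

#' Conditional-accuracy part of the spatiotemporal maps
#'
#' @param events A \code{"crossing_events"} object.
#' @return Matrix CA (spatial thresholds x temporal bins; NA where no
#'   events).
#' @export
stsa_ca <- function(events) stsa_maps(events)$CA

#' Scale hazard maps to a shared maximum
#'
#' Divides every hazard map by the single maximum hazard across all supplied
#' condition maps, so the global maximum becomes exactly 1 and cells remain
#' comparable within and across conditions (relative order is preserved by
#' the positive scalar).
#'
#' @param maps A list of \code{"stsa_maps"} (one per condition), or a single
#'   one.
#' @return The same structure with \code{H} rescaled and \code{scale} set to
#'   the shared maximum. All-zero hazards are an error.
#' @export
scale_maps <- function(maps) {
  single <- inherits(maps, "stsa_maps")
  if (single) maps <- list(maps)
  stopifnot(all(vapply(maps, inherits, logical(1), "stsa_maps")))
  hmax <- max(vapply(maps, function(m) max(m$H), numeric(1)))
  if (hmax <= 0) stop("cannot scale: all hazard maps are zero")
  maps <- lapply(maps, function(m) {
    m$H <- m$H / hmax
    m$scale <- hmax
    m
  })
  if (single) maps[[1]] else maps
}

#' @export
print.stsa_maps <- function(x, ...) {
  cat(sprintf("StSA maps: %d thresholds x %d time bins, %d trials, %d events\n",
              nrow(x$H), ncol(x$H), x$n_trials, sum(x$n_events)))
  if (!is.na(x$scale))
    cat(sprintf("  hazard scaled by shared maximum %.4f\n", x$scale))
  cat(sprintf("  max H %.3f; CA defined in %d / %d cells\n",
              max(x$H), sum(!is.na(x$CA)), length(x$CA)))
  invisible(x)
}

#' Early-window trial counts
#'
#' Number of DISTINCT trials with at least one crossing event inside a time
#' window (default the first 500 ms, right-closed), per grouping cell — the
#' robustness tally behind early-movement claims — plus summary statistics
#' of the counts per grouping variable.
#'
#' @param events A \code{"crossing_events"} object.
#' @param window_ms Length-2 numeric, window \code{(lo, hi]} in ms.
#' @param by Grouping columns among participant, n_back, trial_type.
#' @return List with \code{counts} (one row per group: grouping values and
#'   \code{n_trials}), \code{total_trials} (distinct trials in the window
#'   overall) and \code{summary} (n / mean / sd / min / max of the per-group
#'   counts).
#' @export
early_window_counts <- function(events, window_ms = c(0, 500),
                                by = c("participant", "n_back", "trial_type")) {
  stopifnot(inherits(events, "crossing_events"), length(window_ms) == 2)
  ev <- events$events
  inw <- ev$t_ms > window_ms[1] & ev$t_ms <= window_ms[2]
  evw <- ev[inw, , drop = FALSE]
  groups <- events$trials[events$trials$trial_id %in% unique(evw$trial_id),
                          c("trial_id", "participant", "n_back", "trial_type")]
  if (nrow(groups)) {
    key <- interaction(groups[by], drop = TRUE, sep = ".")
    counts <- do.call(rbind, lapply(split(groups, key), function(g) {
      row <- g[1, by, drop = FALSE]
      row$n_trials <- length(unique(g$trial_id))
      row
    }))
    rownames(counts) <- NULL
  } else {
    counts <- cbind(events$trials[0, by, drop = FALSE],
                    data.frame(n_trials = integer()))
  }
  n <- counts$n_trials
  list(counts = counts,
       total_trials = length(unique(evw$trial_id)),
       summary = data.frame(
         n_groups = nrow(counts),
         mean = if (length(n)) mean(n) else NA_real_,
         sd = if (length(n) > 1) stats::sd(n) else NA_real_,
         min = if (length(n)) min(n) else NA_integer_,
         max = if (length(n)) max(n) else NA_integer_))
}
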