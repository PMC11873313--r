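#' Condition-average movement trajectory
#'
#' Mean signed position over trials at each point of a regular time grid.
#' A trial contributes at a time point only while its recording lasts: there
#' is no padding or extrapolation, so late time points average fewer
#' trajectories, and the number contributing is reported alongside the mean.
#' Within a recording, positions are linearly interpolated onto the grid.
#'
#' @param dataset An \code{\link{stsa_dataset}} (or a trajectory data.frame
#'   with columns \code{trial_id}, \code{t_ms}, \code{x_m}).
#' @param trial_ids Optional subset of trials to average.
#' @param step_ms Time-grid step in milliseconds (default 10).
#' @return data.frame with columns \code{t_ms}, \code{mean_x_m},
#'   \code{n_contributing}.
#' @export
average_trajectories <- function(dataset, trial_ids = NULL, step_ms = 10) {
  traj <- if (inherits(dataset, "stsa_dataset")) dataset$trajectories else
    as.data.frame(dataset)
  if (!is.null(trial_ids))
    traj <- traj[traj$trial_id %in% trial_ids, , drop = FALSE]
  if (!nrow(traj)) stop("no trajectories to average")
  by_trial <- split(traj[c("t_ms", "x_m")], traj$trial_id)
  t_max <- max(traj$t_ms)
  grid_t <- seq(0, t_max, by = step_ms)
  acc_sum <- numeric(length(grid_t))
  acc_n <- integer(length(grid_t))
  for (tr in by_trial) {
    within <- grid_t >= min(tr$t_ms) & grid_t <= max(tr$t_ms)
    if (!any(within)) next
    xi <- if (nrow(tr) == 1) rep(tr$x_m, sum(within)) else
      stats::approx(tr$t_ms, tr$x_m, xout = grid_t[within])$y
    acc_sum[within] <- acc_sum[within] + xi
    acc_n[within] <- acc_n[within] + 1L
  }
  data.frame(t_ms = grid_t,
             mean_x_m = ifelse(acc_n > 0, acc_sum / pmax(acc_n, 1L), NA_real_),
             n_contributing = acc_n)
}

#' Spatiotemporal occupancy counts
#'
#' Counts trajectory visits per cell of a fine space-by-time grid, the
#' single-trial heat-map layer of the pipeline. With the default
#' \code{per_trajectory} counting a cell increments at most once per trial
#' ("number of trajectories that visit"); \code{per_sample} counts every
#' sample and is kept for diagnostics. Samples outside the spatial or
#' temporal range are dropped and tallied in the report.
#'
#' @param dataset An \code{\link{stsa_dataset}} or trajectory data.frame.
#' @param grid An \code{\link{occupancy_grid}}.
#' @param counting \code{"per_trajectory"} (default) or \code{"per_sample"}.
#' @return Object of class \code{"stsa_occupancy"}: list with \code{counts}
#'   (matrix, rows = spatial bins from \code{x_min} up, cols = time bins),
#'   \code{n_dropped}, \code{n_trials}, the grid and the counting mode.
#' @export
occupancy <- function(dataset, grid = occupancy_grid(),
                      counting = c("per_trajectory", "per_sample")) {
  counting <- match.arg(counting)
  stopifnot(inherits(grid, "occupancy_grid"))
  traj <- if (inherits(dataset, "stsa_dataset")) dataset$trajectories else
    as.data.frame(dataset)
  counts <- matrix(0L, nrow = grid$n_x, ncol = grid$n_t)
  if (!nrow(traj)) {
    return(structure(list(counts = counts, n_dropped = 0L, n_trials = 0L,
                          grid = grid, counting = counting),
                     class = "stsa_occupancy"))
  }
  ix <- findInterval(traj$x_m, grid$x_breaks, rightmost.closed = TRUE)
  # t = 0 (onset sample) is assigned to the first temporal bin
  it <- pmax(ceiling(traj$t_ms / grid$t_bin_ms), 1)
  ok <- ix >= 1 & ix <= grid$n_x & traj$t_ms <= grid$t_max_ms & traj$t_ms >= 0
  n_dropped <- sum(!ok)
  cell <- (it[ok] - 1) * grid$n_x + ix[ok]
  if (counting == "per_trajectory") {
    keep <- !duplicated(data.frame(traj$trial_id[ok], cell))
    cell <- cell[keep]
  }
  tab <- tabulate(cell, nbins = grid$n_x * grid$n_t)
  counts <- matrix(as.integer(tab), nrow = grid$n_x, ncol = grid$n_t)
  structure(list(counts = counts, n_dropped = n_dropped,
                 n_trials = length(unique(traj$trial_id)),
                 grid = grid, counting = counting),
            class = "stsa_occupancy")
}

#' Log view of occupancy counts
#'
#' Cellwise \code{log10(count + 1)}: zeros stay zero and ordering is
#' preserved, which makes sparse heat maps readable without altering the
#' underlying counts.
#'
#' @param x An \code{"stsa_occupancy"} object or a non-negative count matrix.
#' @return Matrix of transformed values.
#' @export
log_view <- function(x) {
  counts <- if (inherits(x, "stsa_occupancy")) x$counts else x
  if (any(counts < 0)) stop("occupancy counts must be non-negative")
  log10(counts + 1)
}

#' @export
print.stsa_occupancy <- function(x, ...) {
  cat(sprintf(
    "Occupancy (%s counting): %d x %d cells, %d trials, %d samples dropped out of range\n",
    x$counting, nrow(x$counts), ncol(x$counts), x$n_trials, x$n_dropped))
  cat(sprintf("  total count %d, max cell count %d\n",
              sum(x$counts), max(x$counts)))
  invisible(x)
}
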