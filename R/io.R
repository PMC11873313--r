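#' Signed box-axis position
#'
#' Collapses the two distances from the moved stimulus to the response boxes
#' into one signed coordinate: \code{(B - A) / 2}, where A is the distance to
#' the Match box and B the distance to the non-Match box. Positive values are
#' nearer the Match box, zero is equidistant, and the magnitude at a box
#' center equals half the box-center separation.
#'
#' @param dist_match Distance A to the Match box, meters, >= 0.
#' @param dist_nonmatch Distance B to the non-Match box, meters, >= 0.
#' @return Signed position in meters (vectorized).
#' @examples
#' signed_position(0, 0.4)    # +0.2, at the Match box
#' signed_position(0.3, 0.1)  # -0.1, nearer the non-Match box
#' @export
signed_position <- function(dist_match, dist_nonmatch) {
  stopifnot(is.numeric(dist_match), is.numeric(dist_nonmatch))
  if (any(dist_match < 0, na.rm = TRUE) || any(dist_nonmatch < 0, na.rm = TRUE))
    stop("distances to the response boxes must be non-negative")
  (dist_nonmatch - dist_match) / 2
}

.TRIAL_COLS <- c("trial_id", "participant", "device", "n_back", "trial_type",
                 "rt_ms", "accuracy")
.TRAJ_COLS <- c("trial_id", "t_ms", "x_m")

#' Trial dataset container
#'
#' Bundles a per-trial table with (optionally) a long-format trajectory table
#' and validates the joint invariants: unique trial ids, n-back levels in
#' 1..3, devices in \{classical, vr\}, trial types in \{match, nonmatch\},
#' positive response times where present, strictly increasing timestamps
#' within each trajectory, and no trajectory rows for classical-device
#' trials. Unfinished trials (no response time, no accuracy) are permitted;
#' they contribute to occupancy and crossing risk sets but not to
#' completed-response survival curves.
#'
#' @param trials data.frame with columns \code{trial_id}, \code{participant},
#'   \code{device}, \code{n_back}, \code{trial_type}, \code{rt_ms},
#'   \code{accuracy} (1/0/NA).
#' @param trajectories Optional data.frame with columns \code{trial_id},
#'   \code{t_ms}, \code{x_m}; rows are sorted by (trial_id, t_ms).
#' @param metadata Free-form provenance list (source file, generator config,
#'   seed).
#' @return An object of class \code{"stsa_dataset"}.
#' @export
stsa_dataset <- function(trials, trajectories = NULL, metadata = list()) {
  trials <- as.data.frame(trials)
  missing_cols <- setdiff(.TRIAL_COLS, names(trials))
  if (length(missing_cols))
    stop("trial table is missing column(s): ", paste(missing_cols, collapse = ", "))
  trials$trial_id <- as.character(trials$trial_id)
  trials$participant <- as.character(trials$participant)
  trials$device <- as.character(trials$device)
  trials$trial_type <- as.character(trials$trial_type)
  trials$n_back <- as.integer(trials$n_back)
  trials$rt_ms <- as.numeric(trials$rt_ms)
  trials$accuracy <- as.integer(trials$accuracy)

  dup <- trials$trial_id[duplicated(trials$trial_id)]
  if (length(dup))
    stop("duplicated trial_id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!trials$device %in% c("classical", "vr")))
    stop("device must be 'classical' or 'vr'")
  if (any(!trials$n_back %in% 1:3))
    stop("n_back must be 1, 2 or 3")
  if (any(!trials$trial_type %in% c("match", "nonmatch")))
    stop("trial_type must be 'match' or 'nonmatch'")
  if (any(trials$rt_ms <= 0, na.rm = TRUE))
    stop("rt_ms must be > 0 where present")
  if (any(!trials$accuracy %in% c(0L, 1L, NA_integer_)))
    stop("accuracy must be 1, 0 or empty")
  if (any(is.na(trials$rt_ms) & !is.na(trials$accuracy)))
    stop("unfinished trials (no rt_ms) cannot carry an accuracy")

  if (!is.null(trajectories) && nrow(trajectories)) {
    trajectories <- as.data.frame(trajectories)
    missing_cols <- setdiff(.TRAJ_COLS, names(trajectories))
    if (length(missing_cols))
      stop("trajectory table is missing column(s): ",
           paste(missing_cols, collapse = ", "))
    trajectories$trial_id <- as.character(trajectories$trial_id)
    trajectories$t_ms <- as.numeric(trajectories$t_ms)
    trajectories$x_m <- as.numeric(trajectories$x_m)
    trajectories <- trajectories[order(trajectories$trial_id, trajectories$t_ms), ,
                                 drop = FALSE]
    rownames(trajectories) <- NULL
    unknown <- setdiff(unique(trajectories$trial_id), trials$trial_id)
    if (length(unknown))
      stop("trajectory rows reference unknown trial_id(s): ",
           paste(unknown, collapse = ", "))
    if (any(trajectories$t_ms < 0))
      stop("trajectory timestamps must be >= 0")
    # after sorting, a violation of strict monotonicity is a duplicated stamp
    bad <- unlist(lapply(split(trajectories$t_ms, trajectories$trial_id),
                         function(t) any(diff(t) <= 0)))
    if (any(bad))
      stop("non-monotone timestamps within trial(s): ",
           paste(names(bad)[bad], collapse = ", "))
    classical <- trials$trial_id[trials$device == "classical"]
    if (any(trajectories$trial_id %in% classical))
      stop("classical-device trials cannot carry trajectories")
  } else {
    trajectories <- data.frame(trial_id = character(), t_ms = numeric(),
                               x_m = numeric())
  }
  structure(list(trials = trials, trajectories = trajectories,
                 metadata = metadata),
            class = "stsa_dataset")
}

#' Read a trial dataset from CSV
#'
#' Reads the documented long-format tables: a trial table (columns
#' \code{trial_id, participant, device, n_back, trial_type, rt_ms, accuracy})
#' and, optionally, a trajectory table (columns \code{trial_id, t_ms, x_m}).
#' Trajectory rows are grouped by trial and sorted by time; all dataset
#' invariants are validated on load.
#'
#' @param trials_path Path to the trial table CSV.
#' @param trajectories_path Optional path to the trajectory table CSV.
#' @return An \code{\link{stsa_dataset}}.
#' @export
read_trials <- function(trials_path, trajectories_path = NULL) {
  if (!file.exists(trials_path)) stop("file not found: ", trials_path)
  trials <- utils::read.csv(trials_path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.TRIAL_COLS, names(trials))
  if (length(missing_cols))
    stop("trial table ", trials_path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  traj <- NULL
  if (!is.null(trajectories_path)) {
    if (!file.exists(trajectories_path))
      stop("file not found: ", trajectories_path)
    traj <- utils::read.csv(trajectories_path, stringsAsFactors = FALSE)
    missing_cols <- setdiff(.TRAJ_COLS, names(traj))
    if (length(missing_cols))
      stop("trajectory table ", trajectories_path, " is missing column(s): ",
           paste(missing_cols, collapse = ", "))
  }
  stsa_dataset(trials, traj,
               metadata = list(source = trials_path,
                               trajectory_source = trajectories_path))
}

#' Write a trial dataset to CSV
#'
#' Inverse of \code{\link{read_trials}}: re-reading the written files
#' reproduces the dataset field by field (exact milliseconds, positions to
#' floating-point round-trip). When the dataset has no trajectories the
#' trajectory file, if requested, is written header-only.
#'
#' @param dataset An \code{\link{stsa_dataset}}.
#' @param trials_path Output path for the trial table.
#' @param trajectories_path Optional output path for the trajectory table.
#' @return Invisibly, the path(s) written.
#' @export
write_trials <- function(dataset, trials_path, trajectories_path = NULL) {
  stopifnot(inherits(dataset, "stsa_dataset"))
  utils::write.csv(dataset$trials, trials_path, row.names = FALSE, na = "")
  paths <- trials_path
  if (!is.null(trajectories_path)) {
    utils::write.csv(dataset$trajectories, trajectories_path,
                     row.names = FALSE, na = "")
    paths <- c(paths, trajectories_path)
  }
  invisible(paths)
}

#' Extract one trial's trajectory
#'
#' @param dataset An \code{\link{stsa_dataset}}.
#' @param trial_id Trial identifier.
#' @return data.frame with columns \code{t_ms}, \code{x_m}, time-sorted.
#' @export
trajectory_of <- function(dataset, trial_id) {
  stopifnot(inherits(dataset, "stsa_dataset"))
  tr <- dataset$trajectories
  out <- tr[tr$trial_id == trial_id, c("t_ms", "x_m"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.stsa_dataset <- function(x, ...) {
  n_traj <- length(unique(x$trajectories$trial_id))
  cat(sprintf("stsa_dataset: %d trials (%d with trajectories, %d samples), %d participant(s)\n",
              nrow(x$trials), n_traj, nrow(x$trajectories),
              length(unique(x$trials$participant))))
  tab <- table(device = x$trials$device, n_back = x$trials$n_back)
  print(tab)
  invisible(x)
}

#' Subset a dataset by trial-level condition
#'
#' @param dataset An \code{\link{stsa_dataset}}.
#' @param keep Logical vector over rows of \code{dataset$trials}, or a
#'   character vector of trial ids.
#' @return The filtered \code{\link{stsa_dataset}}.
#' @export
filter_trials <- function(dataset, keep) {
  stopifnot(inherits(dataset, "stsa_dataset"))
  ids <- if (is.logical(keep)) dataset$trials$trial_id[keep] else as.character(keep)
  trials <- dataset$trials[dataset$trials$trial_id %in% ids, , drop = FALSE]
  traj <- dataset$trajectories[dataset$trajectories$trial_id %in% ids, , drop = FALSE]
  rownames(trials) <- rownames(traj) <- NULL
  stsa_dataset(trials, traj, metadata = dataset$metadata)
}
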