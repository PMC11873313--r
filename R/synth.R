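#' Generator configuration
#'
#' Parameters of the synthetic two-alternative forced-choice trajectory
#' generator. Trials emulate 90 Hz recordings of signed center-to-box
#' distance: a hold at the neutral start during a shifted-lognormal
#' initiation delay, then roughly constant-speed travel toward a box at
#' +/- \code{total_distance}, with per-sample hesitation pauses, optional
#' mid-trial self-correction (a wrong-way excursion that reverses), an early
#' bias to start toward the Match box regardless of the truth, and a
#' per-trial error probability that decides which box the trial finally
#' reaches. Match trials occur with probability \code{match_prob}
#' (default 0.33). Per-level parameters make harder n-back levels slower,
#' more hesitant and less accurate.
#'
#' Reproducibility: a single root seed; each trial draws from its own
#' substream derived from the root seed and a deterministic trial counter,
#' so generation order never changes the data.
#'
#' @param seed Root RNG seed (integer).
#' @param n_participants Number of simulated participants.
#' @param trials_per_condition Trials per participant x n-back level.
#' @param match_prob Probability a trial is a Match trial.
#' @param sample_rate_hz Trajectory sampling rate.
#' @param total_distance_m Distance from neutral start to a box center.
#' @param device \code{"vr"} (trajectories) or \code{"classical"} (response
#'   times only).
#' @param levels Named list of per-n-back parameter lists, each with
#'   \code{delay_shift_ms}, \code{delay_meanlog}, \code{delay_sdlog}
#'   (shifted-lognormal initiation delay), \code{speed_m_s},
#'   \code{hesitation_pause_prob} (per sample), \code{pause_ms} (length-2
#'   range), \code{self_correction_prob}, \code{early_match_bias_prob},
#'   \code{error_prob}.
#' @return List of class \code{"generator_config"}.
#' @export
generator_config <- function(seed = 1L,
                             n_participants = 20,
                             trials_per_condition = 40,
                             match_prob = 0.33,
                             sample_rate_hz = 90,
                             total_distance_m = 0.20,
                             device = c("vr", "classical"),
                             levels = NULL) {
  device <- match.arg(device)
  if (is.null(levels)) {
    levels <- list(
      `1` = list(delay_shift_ms = 250, delay_meanlog = log(180),
                 delay_sdlog = 0.35, speed_m_s = 0.30,
                 hesitation_pause_prob = 0.010, pause_ms = c(100, 400),
                 self_correction_prob = 0.05, early_match_bias_prob = 0.15,
                 error_prob = 0.04),
      `2` = list(delay_shift_ms = 300, delay_meanlog = log(400),
                 delay_sdlog = 0.45, speed_m_s = 0.25,
                 hesitation_pause_prob = 0.020, pause_ms = c(100, 500),
                 self_correction_prob = 0.10, early_match_bias_prob = 0.20,
                 error_prob = 0.10),
      `3` = list(delay_shift_ms = 350, delay_meanlog = log(700),
                 delay_sdlog = 0.55, speed_m_s = 0.20,
                 hesitation_pause_prob = 0.030, pause_ms = c(150, 600),
                 self_correction_prob = 0.15, early_match_bias_prob = 0.30,
                 error_prob = 0.16))
  }
  for (lv in levels) {
    probs <- c(lv$hesitation_pause_prob, lv$self_correction_prob,
               lv$early_match_bias_prob, lv$error_prob)
    stopifnot(all(probs >= 0 & probs <= 1), lv$speed_m_s > 0)
  }
  stopifnot(match_prob >= 0, match_prob <= 1, sample_rate_hz > 0,
            total_distance_m > 0)
  structure(list(seed = as.integer(seed), n_participants = n_participants,
                 trials_per_condition = trials_per_condition,
                 match_prob = match_prob, sample_rate_hz = sample_rate_hz,
                 total_distance_m = total_distance_m, device = device,
                 levels = levels),
            class = "generator_config")
}

#' Read a generator configuration from YAML
#'
#' @param path YAML file; top-level keys are \code{\link{generator_config}}
#'   arguments (per-level parameters under \code{levels: {"1": ..., ...}}).
#' @return A \code{"generator_config"}.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$levels))
    raw$levels <- lapply(raw$levels, function(lv) {
      if (!is.null(lv$pause_ms)) lv$pause_ms <- as.numeric(lv$pause_ms)
      lv
    })
  do.call(generator_config, raw)
}

# deterministic per-trial substream seed: MINSTD-style triple mix of the
# root seed and the trial counter (exact in doubles, result < 2^31)
.trial_seed <- function(root, counter) {
  v <- (as.numeric(root) %% 2147483647) + 1
  for (i in 1:3) v <- (48271 * v) %% 2147483647
  v <- (v + as.numeric(counter)) %% 2147483647
  for (i in 1:3) v <- (48271 * v) %% 2147483647
  as.integer(v)
}

#' Generate one synthetic trial
#'
#' Simulates a single trajectory (or, for the classical device, a response
#' time) from its own RNG substream. See \code{\link{generator_config}} for
#' the movement model. The returned ground truth records every latent draw
#' so recovery tests can compare estimates against it.
#'
#' @param config A \code{"generator_config"}.
#' @param participant Participant id (integer or string).
#' @param n_back Level 1..3.
#' @param counter Deterministic trial counter (drives the RNG substream).
#' @param trial_type Optional; if NULL, drawn as Match with
#'   \code{match_prob}.
#' @return List with \code{trial} (one-row data.frame in the trial-table
#'   schema), \code{trajectory} (data.frame or NULL) and \code{truth} (the
#'   latent variables: delay, first direction, final side, switch position,
#'   bias and self-correction flags, pause count).
#' @export
generate_trial <- function(config, participant, n_back, counter,
                           trial_type = NULL) {
  stopifnot(inherits(config, "generator_config"))
  lv <- config$levels[[as.character(n_back)]]
  if (is.null(lv)) stop("no generator parameters for n_back = ", n_back)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.trial_seed(config$seed, counter))

  if (is.null(trial_type))
    trial_type <- if (stats::runif(1) < config$match_prob) "match" else "nonmatch"
  correct_side <- if (trial_type == "match") 1 else -1
  is_error <- stats::runif(1) < lv$error_prob
  final_side <- if (is_error) -correct_side else correct_side
  biased <- stats::runif(1) < lv$early_match_bias_prob
  first_dir <- if (biased) 1 else final_side
  self_corr <- !biased && first_dir == final_side &&
    stats::runif(1) < lv$self_correction_prob
  delay <- lv$delay_shift_ms +
    stats::rlnorm(1, lv$delay_meanlog, lv$delay_sdlog)
  D <- config$total_distance_m
  trial_id <- sprintf("p%s_n%d_c%06d", participant, as.integer(n_back),
                      as.integer(counter))

  if (config$device == "classical") {
    rt <- delay + stats::rlnorm(1, log(300), 0.2)
    trial <- data.frame(trial_id = trial_id,
                        participant = as.character(participant),
                        device = "classical", n_back = as.integer(n_back),
                        trial_type = trial_type, rt_ms = rt,
                        accuracy = as.integer(!is_error),
                        stringsAsFactors = FALSE)
    return(list(trial = trial, trajectory = NULL,
                truth = list(trial_id = trial_id, delay_ms = delay,
                             first_dir = NA_real_, final_side = final_side,
                             switch_x_m = NA_real_, biased = NA,
                             self_corrected = NA, n_pauses = 0L)))
  }

  # excursion geometry: where the first leg turns around (fraction of D)
  needs_reversal <- first_dir != final_side
  switch_x <- if (needs_reversal) stats::runif(1, 0.25, 0.60) * D
              else if (self_corr) stats::runif(1, 0.10, 0.40) * D
              else NA_real_
  # self-correction: go out with the final side, back toward (or past) the
  # start, then out again
  retreat_x <- if (self_corr) stats::runif(1, -0.10, 0.25) * D else NA_real_

  dt <- 1000 / config$sample_rate_hz
  step <- lv$speed_m_s * dt / 1000
  t <- 0; x <- 0
  ts <- numeric(0); xs <- numeric(0)
  phase <- "hold"       # hold -> leg1 [-> retreat] -> final
  dir <- first_dir
  pause_left <- 0
  n_pauses <- 0L
  max_ms <- 60000
  repeat {
    ts <- c(ts, t); xs <- c(xs, x)
    if (abs(x) >= D || t > max_ms) break
    t <- t + dt
    if (phase == "hold") {
      if (t >= delay) phase <- if (needs_reversal || self_corr) "leg1" else "final"
      next
    }
    if (pause_left > 0) { pause_left <- pause_left - dt; next }
    if (stats::runif(1) < lv$hesitation_pause_prob) {
      pause_left <- stats::runif(1, lv$pause_ms[1], lv$pause_ms[2])
      n_pauses <- n_pauses + 1L
      next
    }
    if (phase == "leg1") {
      x <- x + dir * step
      if (abs(x) >= switch_x) {
        if (needs_reversal) { phase <- "final"; dir <- final_side }
        else { phase <- "retreat"; dir <- -final_side }
      }
    } else if (phase == "retreat") {
      x <- x + dir * step
      if ((final_side > 0 && x <= retreat_x * final_side) ||
          (final_side < 0 && x >= retreat_x * final_side)) {
        phase <- "final"; dir <- final_side
      }
    } else {
      dir <- final_side
      x <- x + dir * step
    }
  }
  finished <- abs(x) >= D
  if (finished) xs[length(xs)] <- sign(x) * D
  rt <- if (finished) t else NA_real_
  acc <- if (finished) as.integer(sign(x) == correct_side) else NA_integer_
  trial <- data.frame(trial_id = trial_id,
                      participant = as.character(participant),
                      device = "vr", n_back = as.integer(n_back),
                      trial_type = trial_type, rt_ms = rt, accuracy = acc,
                      stringsAsFactors = FALSE)
  list(trial = trial,
       trajectory = data.frame(trial_id = trial_id, t_ms = ts, x_m = xs,
                               stringsAsFactors = FALSE),
       truth = list(trial_id = trial_id, delay_ms = delay,
                    first_dir = first_dir, final_side = final_side,
                    switch_x_m = switch_x, biased = biased,
                    self_corrected = self_corr, n_pauses = n_pauses))
}

#' Generate a synthetic dataset with ground truth
#'
#' Balanced participants x n-back design; within each cell,
#' \code{trials_per_condition} trials whose type is drawn Match with
#' probability \code{match_prob}. The manifest records every latent variable
#' (true initiation delay, first movement direction, bias and
#' self-correction flags, final side) per trial, for recovery tests.
#'
#' @param config A \code{\link{generator_config}}.
#' @return List with \code{dataset} (an \code{\link{stsa_dataset}}) and
#'   \code{manifest} (data.frame, one row per trial).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  trials <- list(); trajs <- list(); truths <- list()
  i <- 0L
  nb_levels <- as.integer(names(config$levels))
  for (p in seq_len(config$n_participants)) {
    for (nb in nb_levels) {
      for (k in seq_len(config$trials_per_condition)) {
        i <- i + 1L
        counter <- ((p - 1L) * length(nb_levels) + match(nb, nb_levels) - 1L) *
          config$trials_per_condition + k
        g <- generate_trial(config, sprintf("%02d", p), nb, counter)
        trials[[i]] <- g$trial
        trajs[[i]] <- g$trajectory
        truths[[i]] <- as.data.frame(g$truth, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(trials)) {
    empty <- data.frame(trial_id = character(), participant = character(),
                        device = character(), n_back = integer(),
                        trial_type = character(), rt_ms = numeric(),
                        accuracy = integer())
    return(list(dataset = stsa_dataset(empty,
                                       metadata = list(generator = unclass(config))),
                manifest = data.frame()))
  }
  trial_tab <- do.call(rbind, trials)
  traj_tab <- do.call(rbind, trajs)
  manifest <- do.call(rbind, truths)
  ds <- stsa_dataset(trial_tab, traj_tab,
                     metadata = list(generator = unclass(config),
                                     seed = config$seed))
  list(dataset = ds, manifest = manifest)
}
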