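# Independent brute-force oracles used across tests. These deliberately use
# the most literal counting/arithmetic possible, not the package's code
# paths.

# discrete-time survival curves by direct counting over trials
oracle_survival <- function(rt_ms, correct, w = 100) {
  bins <- ceiling(rt_ms / w)
  K <- max(bins)
  n <- length(bins)
  h <- S <- ca <- numeric(K)
  for (t in seq_len(K)) {
    at_risk <- sum(bins >= t)
    events <- sum(bins == t)
    h[t] <- if (at_risk > 0) events / at_risk else NA_real_
    S[t] <- sum(rt_ms > t * w) / n
    ca[t] <- if (events > 0) sum(correct[bins == t]) / events else NA_real_
  }
  list(h = h, S = S, ca = ca)
}

# per-cell hazard/CA counting over a table of first-crossing events
# events: data.frame(trial_id, threshold_index, bin, correct)
# trial_end_bin: named vector (trial_id -> last bin of recording)
oracle_stsa_maps <- function(events, trial_end_bin, K, TT) {
  H <- matrix(0, K, TT); CA <- matrix(NA_real_, K, TT)
  ids <- names(trial_end_bin)
  for (k in seq_len(K)) {
    ek <- events[events$threshold_index == k, , drop = FALSE]
    for (t in seq_len(TT)) {
      at_risk <- 0L
      for (id in ids) {
        b <- ek$bin[ek$trial_id == id]
        at_risk <- at_risk +
          (if (length(b)) b >= t else trial_end_bin[[id]] >= t)
      }
      ev_t <- ek[ek$bin == t, , drop = FALSE]
      H[k, t] <- if (at_risk > 0) nrow(ev_t) / at_risk else 0
      if (nrow(ev_t)) CA[k, t] <- mean(ev_t$correct)
    }
  }
  list(H = H, CA = CA)
}

# explicit sums-of-squares decomposition for a balanced fully-within
# two-factor repeated-measures design (participant random)
oracle_rm_anova_2w <- function(d, dv, f1, f2, participant = "participant") {
  y <- d[[dv]]
  A <- factor(d[[f1]]); B <- factor(d[[f2]]); S <- factor(d[[participant]])
  a <- nlevels(A); b <- nlevels(B); s <- nlevels(S)
  gm <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean); mS <- tapply(y, S, mean)
  mAB <- tapply(y, list(A, B), mean)
  mAS <- tapply(y, list(A, S), mean)
  mBS <- tapply(y, list(B, S), mean)
  ss_A <- b * s * sum((mA - gm)^2)
  ss_B <- a * s * sum((mB - gm)^2)
  ss_AB <- s * sum((mAB - outer(mA, mB, "+") + gm)^2)
  ss_AS <- b * sum((mAS - outer(mA, mS, "+") + gm)^2)
  ss_BS <- a * sum((mBS - outer(mB, mS, "+") + gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_S <- a * b * sum((mS - gm)^2)
  ss_ABS <- ss_tot - ss_A - ss_B - ss_AB - ss_S - ss_AS - ss_BS
  F_A <- (ss_A / (a - 1)) / (ss_AS / ((a - 1) * (s - 1)))
  F_B <- (ss_B / (b - 1)) / (ss_BS / ((b - 1) * (s - 1)))
  F_AB <- (ss_AB / ((a - 1) * (b - 1))) /
    (ss_ABS / ((a - 1) * (b - 1) * (s - 1)))
  list(ss = c(A = ss_A, B = ss_B, AB = ss_AB),
       ss_err = c(A = ss_AS, B = ss_BS, AB = ss_ABS),
       F = c(A = F_A, B = F_B, AB = F_AB))
}

# tiny valid dataset builders ------------------------------------------------

make_trial_row <- function(trial_id, participant = "p1", device = "vr",
                           n_back = 1, trial_type = "match", rt_ms = 1000,
                           accuracy = 1L) {
  data.frame(trial_id = trial_id, participant = participant, device = device,
             n_back = n_back, trial_type = trial_type, rt_ms = rt_ms,
             accuracy = accuracy, stringsAsFactors = FALSE)
}

# straight-line trajectory: hold at 0 until delay, then constant speed to
# side * dist, sampled every dt ms
make_line_traj <- function(trial_id, delay_ms = 0, speed = 0.2, dist = 0.2,
                           side = 1, dt = 10) {
  t_end <- delay_ms + 1000 * dist / speed
  t <- seq(0, t_end + dt, by = dt)
  x <- pmin(pmax((t - delay_ms), 0) * speed / 1000, dist) * side
  out <- data.frame(trial_id = trial_id, t_ms = t, x_m = x,
                    stringsAsFactors = FALSE)
  out[seq_len(match(dist, abs(x))), ]
}

make_two_trial_dataset <- function() {
  trials <- rbind(
    make_trial_row("t1", trial_type = "match", rt_ms = 1100, accuracy = 1L),
    make_trial_row("t2", trial_type = "nonmatch", rt_ms = 1300, accuracy = 1L))
  traj <- rbind(make_line_traj("t1", delay_ms = 100, side = 1),
                make_line_traj("t2", delay_ms = 300, side = -1))
  stsa_dataset(trials, traj)
}
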