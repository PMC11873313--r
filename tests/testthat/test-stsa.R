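test_that("averaged trajectories respect recording length", {
  tr1 <- make_line_traj("a", delay_ms = 0, speed = 0.2, dist = 0.2)  # 1 s
  tr2 <- make_line_traj("b", delay_ms = 0, speed = 0.1, dist = 0.2)  # 2 s
  ds <- stsa_dataset(rbind(make_trial_row("a", rt_ms = 1000),
                           make_trial_row("b", rt_ms = 2000)),
                     rbind(tr1, tr2))
  avg <- average_trajectories(ds, step_ms = 10)
  # both contribute up to 1 s, only the slow one afterwards
  expect_equal(avg$n_contributing[avg$t_ms <= 1000], rep(2L, 101))
  expect_equal(avg$n_contributing[avg$t_ms > 1000], rep(1L, 100))
  at <- function(t) avg$mean_x_m[avg$t_ms == t]
  expect_equal(at(500), (0.1 + 0.05) / 2)
  expect_equal(at(1500), 0.15)  # the longer trial alone
  # two identical trajectories average to either one
  ds2 <- stsa_dataset(rbind(make_trial_row("a", rt_ms = 1000),
                            make_trial_row("b", rt_ms = 1000)),
                      rbind(tr1, transform(tr1, trial_id = "b")))
  avg2 <- average_trajectories(ds2, step_ms = 10)
  expect_equal(avg2$mean_x_m, tr1$x_m[match(avg2$t_ms, tr1$t_ms)])
  # a mirror pair cancels exactly
  ds3 <- stsa_dataset(rbind(make_trial_row("a", rt_ms = 1000),
                            make_trial_row("b", trial_type = "nonmatch",
                                           rt_ms = 1000)),
                      rbind(tr1, transform(tr1, trial_id = "b",
                                           x_m = -tr1$x_m)))
  expect_true(all(abs(average_trajectories(ds3)$mean_x_m) < 1e-12))
  expect_error(average_trajectories(stsa_dataset(make_trial_row("a"))),
               "no trajectories")
})

test_that("occupancy counting: per-trajectory caps at one visit per trial", {
  # stationary at x = 0 for 1 s
  ds <- stsa_dataset(make_trial_row("s", rt_ms = NA_real_,
                                    accuracy = NA_integer_),
                     data.frame(trial_id = "s", t_ms = seq(0, 1000, 20),
                                x_m = 0))
  occ <- occupancy(ds)
  g <- occ$grid
  central <- findInterval(0, g$x_breaks)
  expect_true(all(occ$counts[-central, ] == 0))
  expect_true(all(occ$counts[central, ] %in% 0:1))
  expect_equal(sum(occ$counts), length(unique(ceiling(
    pmax(seq(0, 1000, 20), 1e-9) / g$t_bin_ms))))
  # empty input
  expect_equal(sum(occupancy(stsa_dataset(make_trial_row("x")))$counts), 0)
})

test_that("per-sample occupancy conserves in-range samples and flags drops", {
  set.seed(5)
  traj <- data.frame(trial_id = "r", t_ms = seq(0, 8000, 11),
                     x_m = runif(728, -0.6, 0.6))
  ds <- stsa_dataset(make_trial_row("r", rt_ms = NA_real_,
                                    accuracy = NA_integer_), traj)
  occ <- occupancy(ds, counting = "per_sample")
  in_range <- sum(abs(traj$x_m) <= 0.404 & traj$t_ms <= 7010)
  expect_equal(sum(occ$counts), in_range)
  expect_equal(occ$n_dropped, nrow(traj) - in_range)
  # per-trajectory counts never exceed the number of trials
  expect_true(all(occupancy(ds)$counts <= 1))
})

test_that("log view maps 0 to 0 and preserves ordering", {
  expect_equal(log_view(matrix(0)), matrix(0))
  expect_equal(log_view(matrix(9)), matrix(1))
  set.seed(6)
  m <- matrix(rpois(60, 4), 6)
  lv <- log_view(m)
  ord <- order(m)
  expect_true(all(diff(lv[ord]) >= 0))
  expect_error(log_view(matrix(-1)), "non-negative")
})

test_that("a straight run to the Match box yields all 20 crossings, correct", {
  tr <- make_line_traj("a", delay_ms = 0, speed = 0.2, dist = 0.2)
  ev <- extract_crossings(tr$t_ms, tr$x_m, "match", trial_id = "a")
  expect_equal(nrow(ev), 20)
  expect_equal(ev$threshold_index, 1:20)
  expect_true(all(ev$correct))
  expect_true(all(diff(ev$bin) >= 0))
  # same trajectory on a non-Match trial: every segment scored incorrect
  expect_true(!any(extract_crossings(tr$t_ms, tr$x_m, "nonmatch")$correct))
})

test_that("a dip before the correct leg splits the scoring by threshold", {
  # out to -0.06 m, back through 0, then to +0.2 m (Match trial)
  t1 <- seq(0, 300, 10); x1 <- -0.06 * t1 / 300
  t2 <- seq(310, 1610, 10); x2 <- -0.06 + 0.26 * (t2 - 300) / 1300
  ev <- extract_crossings(c(t1, t2), c(x1, x2), "match")
  expect_equal(nrow(ev), 20)
  neg <- ev$threshold_index <= 6
  expect_true(all(ev$direction[neg] == -1))
  expect_true(!any(ev$correct[neg]))
  expect_true(all(ev$correct[!neg]))
  # FIRST-crossing property against a brute scan of every sample
  tt <- c(t1, t2); xx <- c(x1, x2)
  for (i in seq_len(nrow(ev))) {
    first <- which(abs(xx) >= ev$threshold_m[i])[1]
    expect_equal(ev$t_ms[i], tt[first])
  }
})

test_that("stationary trajectories yield no events; bad timestamps error", {
  ev <- extract_crossings(c(0, 100, 200), c(0, 0.001, 0.002), "match")
  expect_equal(nrow(ev), 0)
  expect_error(extract_crossings(c(0, 100, 50), c(0, 0.1, 0.2), "match"),
               "non-monotone")
})

test_that("constant-speed crossing times land in the analytic bins", {
  grid <- stsa_grid()
  for (case in list(c(d = 150, v = 0.25), c(d = 420, v = 0.1),
                    c(d = 0, v = 0.33))) {
    tr <- make_line_traj("a", delay_ms = case[["d"]], speed = case[["v"]],
                         dist = 0.2, dt = 1000 / 90)
    ev <- extract_crossings(tr$t_ms, tr$x_m, "match", grid)
    analytic <- case[["d"]] + 1000 * grid$thresholds_m / case[["v"]]
    # sample-exact detection: within one sample period above the analytic time
    expect_true(all(ev$t_ms >= analytic - 1e-9))
    expect_true(all(ev$t_ms - analytic <= 1000 / 90 + 1e-9))
    expect_equal(ev$bin, bin_index(ev$t_ms, grid$temporal))
  }
})

test_that("spatiotemporal hazard matches direct counting", {
  # two trials crossing threshold k in bins 2 and 3
  trials <- rbind(make_trial_row("a", rt_ms = 250),
                  make_trial_row("b", rt_ms = 350))
  traj <- rbind(make_line_traj("a", delay_ms = 100, speed = 2, dist = 0.2,
                               dt = 50),
                make_line_traj("b", delay_ms = 220, speed = 2, dist = 0.2,
                               dt = 50))
  ds <- stsa_dataset(trials, traj)
  ev <- crossing_events(ds)
  m <- stsa_maps(ev)
  # threshold 20 (0.2 m) reached in bins 2 and 4 respectively
  k20 <- m$H[20, ]
  b <- ev$events$bin[ev$events$threshold_index == 20]
  expect_equal(k20[b[1]], 0.5)
  expect_equal(k20[b[2]], 1)
  # full map against the brute-force per-cell oracle
  end_bin <- setNames(ev$trials$end_bin, ev$trials$trial_id)
  o <- oracle_stsa_maps(ev$events, end_bin, 20, 10)
  expect_equal(m$H[, 1:10], o$H)
  expect_equal(m$CA[, 1:10], o$CA)
})

test_that("hazard rows obey the product identity when no trial ends early", {
  set.seed(404)
  n <- 40
  trials <- do.call(rbind, lapply(seq_len(n), function(i)
    make_trial_row(sprintf("t%02d", i),
                   trial_type = sample(c("match", "nonmatch"), 1),
                   rt_ms = NA_real_, accuracy = NA_integer_)))
  traj <- do.call(rbind, lapply(seq_len(n), function(i) {
    tr <- make_line_traj(sprintf("t%02d", i),
                         delay_ms = runif(1, 0, 800),
                         speed = runif(1, 0.1, 0.4), dist = 0.2, dt = 11)
    tr
  }))
  ds <- stsa_dataset(trials, traj)
  ev <- crossing_events(ds)
  m <- stsa_maps(ev)
  for (k in c(1, 7, 20)) {
    evk <- ev$events[ev$events$threshold_index == k, ]
    # every trial crosses k here, so survival of row k is exact
    expect_equal(nrow(evk), n)
    for (t in c(3, 8, 14)) {
      frac_not_crossed <- mean(evk$bin > t)
      expect_equal(prod(1 - m$H[k, 1:t]), frac_not_crossed)
    }
  }
})

test_that("conditional accuracy cells are plain event means", {
  ds <- make_two_trial_dataset()
  ev <- crossing_events(ds)
  m <- stsa_maps(ev)
  expect_true(all(m$CA[!is.na(m$CA)] >= 0 & m$CA[!is.na(m$CA)] <= 1))
  expect_identical(is.na(m$CA), m$n_events == 0)
  # one correct + one incorrect event in the same cell -> 0.5
  trials <- rbind(make_trial_row("a", trial_type = "match", rt_ms = 1100),
                  make_trial_row("b", trial_type = "nonmatch", rt_ms = 1100))
  traj <- rbind(make_line_traj("a", delay_ms = 100, side = 1),
                make_line_traj("b", delay_ms = 100, side = 1))
  m2 <- stsa_maps(crossing_events(stsa_dataset(trials, traj)))
  defined <- which(!is.na(m2$CA), arr.ind = TRUE)
  expect_true(all(m2$CA[defined] == 0.5))
})

test_that("scaling divides every map by the one global maximum", {
  ds <- make_two_trial_dataset()
  ev <- crossing_events(ds)
  m_match <- stsa_maps(filter_events(ev, trial_type = "match"))
  m_non <- stsa_maps(filter_events(ev, trial_type = "nonmatch"))
  scaled <- scale_maps(list(match = m_match, nonmatch = m_non))
  gmax <- max(max(m_match$H), max(m_non$H))
  expect_equal(max(vapply(scaled, function(m) max(m$H), numeric(1))), 1)
  expect_equal(scaled$match$H, m_match$H / gmax)
  expect_equal(scaled$nonmatch$H, m_non$H / gmax)
  # ordering of any two cells is preserved
  expect_equal(order(scaled$match$H), order(m_match$H))
  # single map: its own max becomes 1
  s1 <- scale_maps(m_match)
  expect_equal(max(s1$H), 1)
  # all-zero maps cannot be scaled
  z <- m_match; z$H[] <- 0
  expect_error(scale_maps(z), "zero")
})

test_that("early-window counts are distinct-trial cardinalities", {
  set.seed(99)
  cfg <- generator_config(seed = 21, n_participants = 3,
                          trials_per_condition = 8)
  ds <- generate_dataset(cfg)$dataset
  ev <- crossing_events(ds)
  res <- early_window_counts(ev)
  # brute force: per group, count unique trials with an event in (0, 500]
  evw <- ev$events[ev$events$t_ms > 0 & ev$events$t_ms <= 500, ]
  meta <- ev$trials[match(unique(evw$trial_id), ev$trials$trial_id), ]
  brute <- table(interaction(meta[c("participant", "n_back", "trial_type")],
                             drop = TRUE, sep = "."))
  got <- setNames(res$counts$n_trials,
                  as.character(interaction(res$counts[c("participant", "n_back",
                                                        "trial_type")],
                                           sep = ".")))
  brute_v <- c(brute)
  expect_setequal(names(got), names(brute_v))
  expect_equal(unname(got[names(brute_v)]), unname(as.integer(brute_v)))
  expect_equal(res$total_trials, length(unique(evw$trial_id)))
  expect_equal(res$summary$n_groups, nrow(res$counts))
  # a trial with many events in the window still counts once
  tr <- make_line_traj("fast", delay_ms = 0, speed = 1, dist = 0.2)
  ds1 <- stsa_dataset(make_trial_row("fast", rt_ms = 200), tr)
  r1 <- early_window_counts(crossing_events(ds1))
  expect_equal(r1$total_trials, 1)
  expect_equal(r1$counts$n_trials, 1)
  # no events before the window's end
  tr2 <- make_line_traj("slow", delay_ms = 600, speed = 1, dist = 0.2)
  ds2 <- stsa_dataset(make_trial_row("slow", rt_ms = 800), tr2)
  expect_equal(early_window_counts(crossing_events(ds2))$total_trials, 0)
})
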