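#' Repeated-measures / mixed ANOVA with Greenhouse-Geisser correction
#'
#' Classical univariate sums-of-squares decomposition for balanced designs
#' with the participant as random factor: any number of fully crossed
#' within-participant factors, optionally crossed with between-participant
#' factors. Per effect it reports F, numerator/denominator df, p, and
#' partial eta squared (SS_effect / (SS_effect + SS_error)). For every
#' effect whose within-participant part has 2 or more numerator df, the
#' Greenhouse-Geisser epsilon is estimated from the effect-specific
#' orthonormal-contrast covariance of the participant-by-cell means and a
#' sphericity-corrected p (both df multiplied by epsilon) is reported
#' alongside the uncorrected one.
#'
#' Rows are aggregated to one cell mean per participant and cell before
#' fitting, so either cell means or trial-level data may be passed; a
#' participant missing any cell is a design error.
#'
#' @param data Long data.frame.
#' @param dv Name of the numeric response column.
#' @param within Character vector of within-participant factor columns.
#' @param between Optional character vector of between-participant factor
#'   columns.
#' @param participant Name of the participant column.
#' @return Object of class \code{"rm_anova"}: a list with \code{table}
#'   (one row per effect: \code{effect}, \code{df_num}, \code{df_den},
#'   \code{ss}, \code{ss_error}, \code{F}, \code{p}, \code{pes},
#'   \code{gg_epsilon}, \code{p_gg}) and design metadata. Zero error
#'   variance leaves F and p as NA with a warning.
#' @export
rm_anova <- function(data, dv, within, between = NULL,
                     participant = "participant") {
  data <- as.data.frame(data)
  all_f <- c(within, between, participant)
  stopifnot(dv %in% names(data), all(all_f %in% names(data)))
  if (length(within) < 1) stop("at least one within-participant factor is required")
  d <- data[c(all_f, dv)]
  for (f in all_f) d[[f]] <- factor(d[[f]])
  names(d)[names(d) == dv] <- ".y"
  if (any(is.na(d$.y))) stop("missing values in the response")

  # one between-group per participant
  if (length(between)) {
    bkey <- interaction(d[between], drop = FALSE, sep = ".")
    per_p <- tapply(as.character(bkey), d[[participant]],
                    function(v) length(unique(v)))
    if (any(per_p != 1))
      stop("participant(s) appear in more than one between-participant cell")
  }

  # aggregate to participant x cell means; reject missing cells
  cell_key <- interaction(d[within], drop = FALSE, sep = "\r")
  agg <- stats::aggregate(d$.y,
                          by = c(d[c(participant, between)],
                                 list(.cell = cell_key)),
                          FUN = mean)
  names(agg)[names(agg) == "x"] <- ".y"
  n_cells <- prod(vapply(d[within], nlevels, integer(1)))
  counts <- table(agg[[participant]])
  if (any(counts != n_cells))
    stop("unbalanced design: participant(s) missing within-cell(s): ",
         paste(names(counts)[counts != n_cells], collapse = ", "))
  # re-expand the cell key into its factors
  cell_levels <- do.call(expand.grid,
                         c(lapply(d[within], levels),
                           list(KEEP.OUT.ATTRS = FALSE,
                                stringsAsFactors = FALSE)))
  names(cell_levels) <- within
  cell_lab <- interaction(cell_levels, drop = FALSE, sep = "\r")
  idx <- match(as.character(agg$.cell), as.character(cell_lab))
  for (f in within)
    agg[[f]] <- factor(cell_levels[[f]][idx], levels = levels(d[[f]]))

  rhs <- paste(c(between, within), collapse = " * ")
  err <- paste0("Error(", participant, "/(",
                paste(within, collapse = " * "), "))")
  form <- stats::as.formula(paste(".y ~", rhs, "+", err))
  fit <- stats::aov(form, data = agg)
  strata <- summary(fit)

  rows <- list()
  for (st in strata) {
    tab <- st[[1]]
    effs <- trimws(rownames(tab))
    resid_i <- which(effs == "Residuals")
    ss_err <- if (length(resid_i)) tab[resid_i, "Sum Sq"] else NA_real_
    df_err <- if (length(resid_i)) tab[resid_i, "Df"] else NA_real_
    for (i in setdiff(seq_along(effs), resid_i)) {
      rows[[length(rows) + 1]] <- data.frame(
        effect = effs[i], df_num = tab[i, "Df"], df_den = df_err,
        ss = tab[i, "Sum Sq"], ss_error = ss_err, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  # an error SS at floating-point noise level means F is undefined
  ss_tot <- sum((agg$.y - mean(agg$.y))^2)
  zero_err <- !is.na(res$ss_error) &
    res$ss_error <= max(1e-12 * ss_tot, 1e-25)
  if (any(zero_err))
    warning("zero error variance for effect(s): ",
            paste(res$effect[zero_err], collapse = ", "),
            "; F undefined")
  res$F <- ifelse(zero_err, NA_real_,
                  (res$ss / res$df_num) / (res$ss_error / res$df_den))
  res$p <- ifelse(is.na(res$F), NA_real_,
                  stats::pf(res$F, res$df_num, res$df_den, lower.tail = FALSE))
  res$pes <- ifelse(res$ss + res$ss_error > 0,
                    res$ss / (res$ss + res$ss_error), NA_real_)

  # Greenhouse-Geisser epsilon per within-part of each effect
  res$gg_epsilon <- NA_real_
  res$p_gg <- NA_real_
  eps_cache <- list()
  for (i in seq_len(nrow(res))) {
    parts <- strsplit(res$effect[i], ":", fixed = TRUE)[[1]]
    wpart <- intersect(parts, within)
    if (!length(wpart)) next
    d_eff <- prod(vapply(agg[wpart], nlevels, integer(1)) - 1L)
    if (d_eff < 2) { res$gg_epsilon[i] <- 1; res$p_gg[i] <- res$p[i]; next }
    key <- paste(sort(wpart), collapse = ":")
    if (is.null(eps_cache[[key]]))
      eps_cache[[key]] <- .gg_epsilon(agg, wpart, between, participant)
    eps <- eps_cache[[key]]
    res$gg_epsilon[i] <- eps
    res$p_gg[i] <- if (is.na(res$F[i]) || is.na(eps)) NA_real_ else
      stats::pf(res$F[i], eps * res$df_num[i], eps * res$df_den[i],
                lower.tail = FALSE)
  }
  rownames(res) <- NULL
  structure(list(table = res, within = within, between = between,
                 participant = participant,
                 n_participants = length(unique(agg[[participant]]))),
            class = "rm_anova")
}

# Greenhouse-Geisser epsilon for the within-factor subset `wpart`:
# participant-by-cell means averaged over the other within factors, pooled
# (within between-groups) covariance, effect contrasts as the kronecker
# product of per-factor orthonormalized Helmert contrasts.
.gg_epsilon <- function(agg, wpart, between, participant) {
  cells <- do.call(expand.grid,
                   c(lapply(agg[wpart], levels),
                     list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  cell_of <- interaction(lapply(wpart, function(f) agg[[f]]),
                         drop = FALSE, sep = "\r")
  cell_lab <- interaction(cells, drop = FALSE, sep = "\r")
  pids <- sort(unique(as.character(agg[[participant]])))
  Y <- matrix(NA_real_, length(pids), nrow(cells),
              dimnames = list(pids, NULL))
  means <- tapply(agg$.y,
                  list(as.character(agg[[participant]]),
                       as.character(cell_of)),
                  mean)
  Y[] <- means[pids, as.character(cell_lab)]
  # center within between-group (grand-center if purely within)
  if (length(between)) {
    grp <- tapply(as.character(interaction(agg[between], sep = ".")),
                  as.character(agg[[participant]]), function(v) v[1])[pids]
  } else grp <- rep("all", length(pids))
  for (g in unique(grp)) {
    rows <- grp == g
    Y[rows, ] <- sweep(Y[rows, , drop = FALSE], 2,
                       colMeans(Y[rows, , drop = FALSE]))
  }
  S <- crossprod(Y) / (length(pids) - length(unique(grp)))
  Cs <- lapply(wpart, function(f) {
    L <- nlevels(agg[[f]])
    qr.Q(qr(stats::contr.helmert(L)))
  })
  C <- Reduce(function(a, b) kronecker(b, a), Cs)  # first factor fastest
  M <- t(C) %*% S %*% C
  d <- ncol(C)
  tr <- sum(diag(M))
  if (tr <= 0) return(NA_real_)
  eps <- tr^2 / (d * sum(M * M))
  min(max(eps, 1 / d), 1)
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (%d participants; within: %s%s)\n",
              x$n_participants, paste(x$within, collapse = " x "),
              if (length(x$between))
                paste0("; between: ", paste(x$between, collapse = " x "))
              else ""))
  tab <- x$table
  out <- data.frame(effect = tab$effect,
                    F = round(tab$F, 3),
                    df = sprintf("(%g, %g)", tab$df_num, tab$df_den),
                    p = signif(tab$p, 3),
                    pes = round(tab$pes, 3),
                    gg_eps = round(tab$gg_epsilon, 3),
                    p_gg = signif(tab$p_gg, 3))
  print(out, row.names = FALSE)
  invisible(x)
}

#' Post-hoc paired contrasts
#'
#' Paired t tests on per-participant means for every level pair of one
#' within-participant factor, with Holm (default) or Bonferroni p
#' correction. A pair with zero-variance differences but a nonzero mean
#' difference is degenerate: its t and p are NA and the row is flagged.
#'
#' @param data Long data.frame (cell means or trial rows; aggregated to
#'   participant means per level).
#' @param dv Response column name.
#' @param factor_name Factor column to compare.
#' @param participant Participant column name.
#' @param correction \code{"holm"} or \code{"bonferroni"}.
#' @return data.frame with one row per pair: \code{level_1}, \code{level_2},
#'   \code{m_diff}, \code{se}, \code{t}, \code{df}, \code{p},
#'   \code{p_corrected}, \code{degenerate}.
#' @export
posthoc_pairwise <- function(data, dv, factor_name,
                             participant = "participant",
                             correction = c("holm", "bonferroni")) {
  correction <- match.arg(correction)
  data <- as.data.frame(data)
  stopifnot(dv %in% names(data), factor_name %in% names(data))
  f <- factor(data[[factor_name]])
  means <- tapply(data[[dv]], list(as.character(data[[participant]]),
                                   as.character(f)), mean)
  if (any(is.na(means)))
    stop("every participant needs a value in every level of ", factor_name)
  if (nrow(means) < 2) stop("at least 2 participants required")
  pairs <- utils::combn(levels(f), 2)
  rows <- apply(pairs, 2, function(pr) {
    dd <- means[, pr[1]] - means[, pr[2]]
    n <- length(dd)
    m <- mean(dd)
    se <- stats::sd(dd) / sqrt(n)
    # zero-variance differences (up to floating-point noise) with a nonzero
    # mean have no error term: t is undefined
    degenerate <- se <= 1e-8 * abs(m) && m != 0
    tval <- if (degenerate) NA_real_ else if (se == 0) 0 else m / se
    p <- if (is.na(tval)) NA_real_ else
      2 * stats::pt(-abs(tval), df = n - 1)
    data.frame(level_1 = pr[1], level_2 = pr[2], m_diff = m, se = se,
               t = tval, df = n - 1, p = p, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$degenerate))
    warning("zero-variance difference(s) with nonzero mean: t undefined")
  out$p_corrected <- stats::p.adjust(out$p, method = correction)
  rownames(out) <- NULL
  out
}

#' Conditional-accuracy table for windowed inference
#'
#' Aggregates crossing events into the cell table the windowed ANOVAs
#' consume: mean directional correctness per participant x n-back x trial
#' type x spatial bin x time window. Windows are consecutive right-closed
#' intervals from stimulus onset (an event at exactly 500 ms belongs to
#' window 1 under the defaults). Adjacent spatial thresholds can be pooled
#' (\code{pool_thresholds}) to keep early-window cells populated.
#'
#' @param events A \code{"crossing_events"} object.
#' @param n_windows Number of windows (default 8).
#' @param window_ms Window length in ms (default 500, i.e. 0-4 s in total).
#' @param pool_thresholds Number of adjacent thresholds per spatial bin
#'   group (default 1 = no pooling).
#' @return data.frame with columns \code{participant}, \code{n_back},
#'   \code{trial_type}, \code{bin}, \code{window}, \code{ca},
#'   \code{n_events}.
#' @export
windowed_ca_table <- function(events, n_windows = 8, window_ms = 500,
                              pool_thresholds = 1) {
  stopifnot(inherits(events, "crossing_events"))
  ev <- events$events
  ev$window <- ceiling(ev$t_ms / window_ms)
  ev <- ev[ev$window >= 1 & ev$window <= n_windows, , drop = FALSE]
  ev$bin <- ceiling(ev$threshold_index / pool_thresholds)
  key <- interaction(ev[c("participant", "n_back", "trial_type", "bin",
                          "window")], drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(split(ev, key), function(e) {
    data.frame(participant = e$participant[1], n_back = e$n_back[1],
               trial_type = e$trial_type[1], bin = e$bin[1],
               window = e$window[1], ca = mean(e$correct),
               n_events = nrow(e), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$window, out$participant, out$n_back, out$trial_type,
            out$bin), , drop = FALSE]
}

#' Windowed conditional-accuracy ANOVAs
#'
#' Runs one 2 (trial type) x 3 (n-back) repeated-measures ANOVA per
#' consecutive time window, with the spatial bin as an additional
#' within-participant repeated measure. A participant missing any cell in a
#' window is excluded from that window's ANOVA (and logged); no correction
#' is applied across windows by default. Also emits the display values:
#' per-participant CA means averaged over spatial bins, per window and
#' condition.
#'
#' @param ca_table data.frame as produced by \code{\link{windowed_ca_table}}
#'   (columns \code{participant}, \code{n_back}, \code{trial_type},
#'   \code{bin}, \code{window}, \code{ca}).
#' @param n_windows Number of windows analysed (default: all present,
#'   padded to 8).
#' @param p_adjust Optional correction (\code{"none"}, \code{"holm"})
#'   applied across windows, per effect.
#' @return Object of class \code{"windowed_ca_anova"}: list with
#'   \code{anovas} (per window: an \code{"rm_anova"} or NULL if fewer than
#'   2 complete participants), \code{excluded} (per window: participant ids
#'   dropped), \code{means} (the display values), and an \code{effects}
#'   data.frame of per-window p values for the three effects.
#' @export
windowed_ca_anova <- function(ca_table, n_windows = NULL,
                              p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  ca_table <- as.data.frame(ca_table)
  need <- c("participant", "n_back", "trial_type", "bin", "window", "ca")
  stopifnot(all(need %in% names(ca_table)))
  if (is.null(n_windows)) n_windows <- max(8, max(ca_table$window))
  n_cells <- length(unique(ca_table$n_back)) *
    length(unique(ca_table$trial_type)) * length(unique(ca_table$bin))
  anovas <- vector("list", n_windows)
  excluded <- vector("list", n_windows)
  for (w in seq_len(n_windows)) {
    d <- ca_table[ca_table$window == w, , drop = FALSE]
    if (!nrow(d)) { excluded[[w]] <- character(); next }
    complete <- names(which(table(d$participant) == n_cells))
    excluded[[w]] <- setdiff(unique(d$participant), complete)
    if (length(complete) < 2) next
    d <- d[d$participant %in% complete, , drop = FALSE]
    anovas[[w]] <- tryCatch(
      withCallingHandlers(
        rm_anova(d, dv = "ca",
                 within = c("trial_type", "n_back", "bin")),
        warning = function(wn) invokeRestart("muffleWarning")),
      error = function(e) NULL)
  }
  means_key <- interaction(ca_table[c("participant", "n_back", "trial_type",
                                      "window")], drop = TRUE, sep = "\r")
  means <- do.call(rbind, lapply(split(ca_table, means_key), function(e) {
    data.frame(participant = e$participant[1], n_back = e$n_back[1],
               trial_type = e$trial_type[1], window = e$window[1],
               ca = mean(e$ca), stringsAsFactors = FALSE)
  }))
  rownames(means) <- NULL
  effects <- do.call(rbind, lapply(seq_len(n_windows), function(w) {
    a <- anovas[[w]]
    get_p <- function(eff) {
      if (is.null(a)) return(NA_real_)
      i <- match(eff, a$table$effect)
      if (is.na(i)) NA_real_ else
        if (!is.na(a$table$p_gg[i])) a$table$p_gg[i] else a$table$p[i]
    }
    data.frame(window = w,
               p_trial_type = get_p("trial_type"),
               p_n_back = get_p("n_back"),
               p_interaction = get_p("trial_type:n_back"))
  }))
  if (p_adjust != "none")
    for (col in c("p_trial_type", "p_n_back", "p_interaction"))
      effects[[col]] <- stats::p.adjust(effects[[col]], method = p_adjust)
  structure(list(anovas = anovas, excluded = excluded, means = means,
                 effects = effects, n_windows = n_windows),
            class = "windowed_ca_anova")
}

#' @export
print.windowed_ca_anova <- function(x, ...) {
  cat(sprintf("Windowed conditional-accuracy ANOVAs (%d windows)\n",
              x$n_windows))
  eff <- x$effects
  eff$n_excluded <- vapply(x$excluded[seq_len(x$n_windows)],
                           length, integer(1))
  print(eff, row.names = FALSE, digits = 3)
  invisible(x)
}
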