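#' Discrete-time survival curves for completed responses
#'
#' Estimates the hazard function h(t) = P(T = t | T >= t), the survivor
#' function S(t) = P(T > t) and the conditional accuracy function
#' ca(t) = P(correct | T = t) over left-open right-closed time bins, from the
#' completed response times of one condition pooled across participants.
#' No observation is dropped: counts run over every bin up to the largest
#' response time, and the display window (default 70 bins) only truncates
#' plots and printed tables, never the estimates. There is no Kaplan-Meier
#' censoring machinery because every included trial has a complete event
#' time.
#'
#' @param rt_ms Completed response times in milliseconds (> 0).
#' @param correct Logical or 0/1 vector of final accuracies, same length.
#' @param grid A \code{\link{temporal_grid}}.
#' @return An object of class \code{"survival_curves"}: a list with a
#'   per-bin data.frame \code{curves} (columns \code{bin}, \code{t_upper_ms},
#'   \code{n_at_risk}, \code{n_events}, \code{n_correct}, \code{h}, \code{S},
#'   \code{ca}; \code{ca} is NA exactly where a bin has no events),
#'   \code{median_rt_ms} (linear interpolation of S at 0.5, NA under heavy
#'   censoring), \code{mask_from_bin} (first bin with S below 5\%, for
#'   display greying), \code{n} and the grid.
#' @examples
#' sc <- estimate_survival(c(150, 150, 250, 350), c(1, 1, 1, 1))
#' sc$curves$h[1:4]  # 0, 0.5, 0.5, 1
#' @export
estimate_survival <- function(rt_ms, correct, grid = temporal_grid()) {
  stopifnot(inherits(grid, "temporal_grid"))
  if (length(rt_ms) < 1) stop("estimate_survival() needs at least one trial")
  if (length(correct) != length(rt_ms))
    stop("rt_ms and correct must have the same length")
  if (any(is.na(rt_ms))) stop("every trial must have a completed response time")
  if (any(is.na(correct))) stop("every trial must have a final accuracy")
  correct <- as.integer(as.logical(correct))
  bins <- bin_index(rt_ms, grid)
  n <- length(bins)
  n_bins <- max(max(bins), grid$display_bins)

  n_events <- tabulate(bins, nbins = n_bins)
  n_correct <- vapply(seq_len(n_bins),
                      function(k) sum(correct[bins == k]), integer(1))
  n_at_risk <- n - c(0L, cumsum(n_events)[-n_bins])
  h <- ifelse(n_at_risk > 0, n_events / n_at_risk, NA_real_)
  S <- (n - cumsum(n_events)) / n
  ca <- ifelse(n_events > 0, n_correct / n_events, NA_real_)

  curves <- data.frame(bin = seq_len(n_bins),
                       t_upper_ms = seq_len(n_bins) * grid$bin_ms,
                       n_at_risk = n_at_risk, n_events = n_events,
                       n_correct = n_correct, h = h, S = S, ca = ca)
  out <- structure(list(curves = curves, n = n, grid = grid,
                        median_rt_ms = NA_real_, mask_from_bin = NA_integer_),
                   class = "survival_curves")
  out$median_rt_ms <- median_rt(out)
  out$mask_from_bin <- mask_from(out)
  out
}

#' Median response time from a survivor function
#'
#' Linear interpolation of S(t) against bin upper edges at level 0.5,
#' starting from S = 1 at t = 0; an exact hit on 0.5 returns that bin edge.
#' If S never reaches 0.5 (heavy censoring) the median is undefined and
#' \code{NA_real_} is returned rather than an error.
#'
#' @param curves A \code{"survival_curves"} object.
#' @return Median RT in milliseconds, or \code{NA_real_}.
#' @export
median_rt <- function(curves) {
  stopifnot(inherits(curves, "survival_curves"))
  S <- c(1, curves$curves$S)
  t <- c(0, curves$curves$t_upper_ms)
  i <- which(S <= 0.5)[1]
  if (is.na(i)) return(NA_real_)
  if (S[i] == 0.5) return(t[i])
  # S[i-1] > 0.5 > S[i]: interpolate on the segment
  t[i - 1] + (t[i] - t[i - 1]) * (S[i - 1] - 0.5) / (S[i - 1] - S[i])
}

#' Display-masking bin
#'
#' First bin whose survivor value drops below a threshold (default 5\% of
#' trials). Downstream plots grey every bin from that ordinal on, to
#' de-emphasize estimates based on a vanishing share of trials; the
#' estimates themselves are never altered.
#'
#' @param curves A \code{"survival_curves"} object.
#' @param threshold Survivor threshold, default 0.05.
#' @return Bin ordinal, or \code{NA_integer_} if S never drops below the
#'   threshold.
#' @export
mask_from <- function(curves, threshold = 0.05) {
  stopifnot(inherits(curves, "survival_curves"))
  i <- which(curves$curves$S < threshold)[1]
  if (is.na(i)) NA_integer_ else curves$curves$bin[i]
}

#' @export
print.survival_curves <- function(x, ...) {
  cat(sprintf("Discrete-time survival curves: %d trials, %g ms bins\n",
              x$n, x$grid$bin_ms))
  med <- if (is.na(x$median_rt_ms)) "undefined (S > 0.5 throughout)"
         else sprintf("%.1f ms", x$median_rt_ms)
  cat("  median RT:", med, "\n")
  if (!is.na(x$mask_from_bin))
    cat(sprintf("  <5%% of trials remain from bin %d (displays greyed)\n",
                x$mask_from_bin))
  shown <- x$curves[x$curves$n_events > 0, , drop = FALSE]
  shown <- utils::head(shown[shown$bin <= x$grid$display_bins, ], 10)
  print(shown, row.names = FALSE, digits = 3)
  if (sum(x$curves$n_events > 0) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
summary.survival_curves <- function(object, ...) {
  cc <- object$curves
  list(n = object$n,
       median_rt_ms = object$median_rt_ms,
       mask_from_bin = object$mask_from_bin,
       last_event_bin = max(cc$bin[cc$n_events > 0]),
       overall_accuracy = sum(cc$n_correct) / object$n)
}

#' Survival curves per condition
#'
#' Splits the completed trials of a dataset by grouping factors and estimates
#' one set of curves per condition cell (pooled across participants, the
#' default aggregation of the method; split by participant as well to feed
#' per-participant statistics).
#'
#' @param dataset An \code{\link{stsa_dataset}}.
#' @param by Character vector of trial-table columns to split on.
#' @param grid A \code{\link{temporal_grid}}.
#' @return Named list of \code{"survival_curves"}, names built from the
#'   grouping values (\code{.}-separated). Cells with no completed trials are
#'   omitted.
#' @export
survival_by <- function(dataset, by = c("device", "n_back", "trial_type"),
                        grid = temporal_grid()) {
  stopifnot(inherits(dataset, "stsa_dataset"))
  tr <- dataset$trials
  missing_cols <- setdiff(by, names(tr))
  if (length(missing_cols))
    stop("unknown grouping column(s): ", paste(missing_cols, collapse = ", "))
  done <- tr[!is.na(tr$rt_ms) & !is.na(tr$accuracy), , drop = FALSE]
  if (!nrow(done)) stop("no completed trials in the dataset")
  key <- interaction(done[by], drop = TRUE, sep = ".")
  lapply(split(done, key), function(d)
    estimate_survival(d$rt_ms, d$accuracy, grid))
}
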