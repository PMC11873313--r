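#' Quartile (1.5 IQR) outlier rejection
#'
#' Keeps values inside the Tukey fences [Q1 - 1.5 IQR, Q3 + 1.5 IQR],
#' applied separately per experimental condition by the caller. Quartiles
#' use linear interpolation (quantile type 7, the R default); the choice is
#' documented because removal counts depend on it. The report expresses the
#' percentage removed relative to the input of THIS pass, matching
#' stage-by-stage trial accounting.
#'
#' @param x Numeric values (e.g. response times of one condition), length
#'   >= 4.
#' @return List of class \code{"trim_result"}: \code{kept}, \code{removed},
#'   \code{n_input}, \code{n_removed}, \code{pct_removed}, \code{lower},
#'   \code{upper}.
#' @examples
#' iqr_trim(c(1, 2, 3, 4, 100))$kept  # 1 2 3 4
#' @export
iqr_trim <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 4) stop("iqr_trim() needs at least 4 values")
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lower <- q[1] - 1.5 * iqr
  upper <- q[2] + 1.5 * iqr
  keep <- x >= lower & x <= upper
  structure(list(kept = x[keep], removed = x[!keep],
                 n_input = length(x), n_removed = sum(!keep),
                 pct_removed = 100 * sum(!keep) / length(x),
                 lower = lower, upper = upper, method = "iqr"),
            class = "trim_result")
}

#' Mean +/- 2 SD outlier rejection
#'
#' Keeps values within two sample standard deviations of the mean, both
#' computed from the input values (n - 1 denominator). Two-sided by default;
#' \code{one_sided = TRUE} removes only the upper tail (values above
#' mean + 2 SD), for the reading in which only slow responses are excluded.
#'
#' @param x Numeric values, length >= 2.
#' @param one_sided Remove only the upper tail.
#' @return A \code{"trim_result"} (see \code{\link{iqr_trim}}).
#' @export
sd_trim <- function(x, one_sided = FALSE) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("sd_trim() needs at least 2 values")
  m <- mean(x)
  s <- stats::sd(x)
  lower <- if (one_sided) -Inf else m - 2 * s
  upper <- m + 2 * s
  keep <- x >= lower & x <= upper
  structure(list(kept = x[keep], removed = x[!keep],
                 n_input = length(x), n_removed = sum(!keep),
                 pct_removed = 100 * sum(!keep) / length(x),
                 lower = lower, upper = upper, method = "sd"),
            class = "trim_result")
}

#' @export
print.trim_result <- function(x, ...) {
  cat(sprintf("%s trim: kept %d of %d (%.2f%% removed), fences [%.4g, %.4g]\n",
              toupper(x$method), length(x$kept), x$n_input, x$pct_removed,
              x$lower, x$upper))
  invisible(x)
}

#' Per-condition variance diagnostics
#'
#' For each condition cell, two complementary spread measures: the variance
#' of the per-participant means (between-participant spread of the cell) and
#' the mean of the per-participant variances (average within-participant
#' trial-to-trial spread). Comparing them across trimmed and untrimmed data
#' shows what trimming does — and does not — do to heterogeneity of
#' variance.
#'
#' @param data Long data.frame with one row per trial.
#' @param value Name of the numeric column (e.g. \code{"rt_ms"}).
#' @param cells Character vector of condition columns.
#' @param participant Name of the participant column.
#' @return data.frame with one row per cell: the cell labels,
#'   \code{var_of_means}, \code{mean_of_vars}, \code{n_participants}.
#' @export
variance_diagnostics <- function(data, value, cells,
                                 participant = "participant") {
  data <- as.data.frame(data)
  stopifnot(value %in% names(data), participant %in% names(data),
            all(cells %in% names(data)))
  key <- interaction(data[cells], drop = TRUE, sep = ".")
  out <- do.call(rbind, lapply(split(data, key), function(d) {
    per_p <- split(d[[value]], d[[participant]])
    means <- vapply(per_p, mean, numeric(1))
    vars <- vapply(per_p, function(v)
      if (length(v) > 1) stats::var(v) else 0, numeric(1))
    row <- d[1, cells, drop = FALSE]
    row$var_of_means <- if (length(means) > 1) stats::var(means) else 0
    row$mean_of_vars <- mean(vars)
    row$n_participants <- length(per_p)
    row
  }))
  rownames(out) <- NULL
  out
}
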