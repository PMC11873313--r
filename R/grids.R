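#' Temporal binning grid
#'
#' Discrete time bins for survival-style analyses. Bins are left-open,
#' right-closed intervals \code{((k-1)w, kw]}, indexed k = 1, 2, ...; with the
#' 100 ms default, bin 37 is the interval (3600, 3700]. \code{display_bins}
#' limits plots and tabular displays only; estimation always runs over the
#' full tail of the data.
#'
#' @param bin_ms Bin width in milliseconds (> 0).
#' @param display_bins Number of bins shown in displays (default 70, i.e. the
#'   first 7 s at 100 ms resolution).
#' @return An object of class \code{"temporal_grid"}.
#' @examples
#' g <- temporal_grid()
#' bin_index(3650, g)  # 37
#' @export
temporal_grid <- function(bin_ms = 100, display_bins = 70) {
  stopifnot(is.numeric(bin_ms), length(bin_ms) == 1, bin_ms > 0,
            is.numeric(display_bins), length(display_bins) == 1,
            display_bins >= 1)
  structure(list(bin_ms = bin_ms, display_bins = as.integer(display_bins)),
            class = "temporal_grid")
}

#' Map a time to its temporal bin
#'
#' Returns the ordinal of the left-open, right-closed bin containing \code{t}:
#' the smallest k with \code{t <= k * bin_ms}. Times beyond the display window
#' return their true ordinal; truncation at \code{display_bins} is purely a
#' display concern.
#'
#' @param t_ms Time(s) in milliseconds, strictly positive.
#' @param grid A \code{\link{temporal_grid}}.
#' @return Integer bin ordinal(s).
#' @export
bin_index <- function(t_ms, grid = temporal_grid()) {
  stopifnot(inherits(grid, "temporal_grid"), is.numeric(t_ms))
  if (any(!is.finite(t_ms)) || any(t_ms <= 0))
    stop("bin_index() requires finite t_ms > 0 (bins are (0, w], (w, 2w], ...)")
  as.integer(ceiling(t_ms / grid$bin_ms))
}

#' Spatiotemporal analysis grid
#'
#' Grid for crossing-event analysis: `n_spatial` incremental spatial
#' thresholds, each a further 5\% of the total travelled distance under the
#' defaults (20 thresholds of 0.01 m tiling 0.20 m), crossed with a temporal
#' grid (default 100 ms x 70 display bins, i.e. 1400 display cells).
#'
#' @param spatial_bin_m Spatial threshold increment in meters.
#' @param n_spatial Number of spatial thresholds.
#' @param temporal A \code{\link{temporal_grid}}.
#' @return An object of class \code{"stsa_grid"} with fields
#'   \code{total_distance_m} (= \code{n_spatial * spatial_bin_m}) and
#'   \code{thresholds_m} (strictly increasing threshold values).
#' @export
stsa_grid <- function(spatial_bin_m = 0.01, n_spatial = 20,
                      temporal = temporal_grid()) {
  stopifnot(spatial_bin_m > 0, n_spatial >= 1,
            inherits(temporal, "temporal_grid"))
  n_spatial <- as.integer(n_spatial)
  structure(list(
    spatial_bin_m = spatial_bin_m,
    n_spatial = n_spatial,
    temporal = temporal,
    total_distance_m = n_spatial * spatial_bin_m,
    thresholds_m = seq_len(n_spatial) * spatial_bin_m
  ), class = "stsa_grid")
}

#' High-resolution occupancy grid
#'
#' Fine spatiotemporal grid for trajectory occupancy heat maps. Defaults give
#' 101 spatial bins of 0.008 m spanning -0.404..0.404 m and 701 temporal bins
#' of 10 ms spanning (0, 7010] ms — 70,801 cells. A sample at exactly t = 0
#' (trajectory onset) is assigned to the first temporal bin.
#'
#' @param x_min,x_max Spatial range in meters.
#' @param n_x Number of spatial bins.
#' @param t_max_ms Upper end of the temporal range in milliseconds.
#' @param n_t Number of temporal bins.
#' @return An object of class \code{"occupancy_grid"}.
#' @export
occupancy_grid <- function(x_min = -0.404, x_max = 0.404, n_x = 101,
                           t_max_ms = 7010, n_t = 701) {
  stopifnot(x_max > x_min, n_x >= 1, t_max_ms > 0, n_t >= 1)
  structure(list(
    x_min = x_min, x_max = x_max, n_x = as.integer(n_x),
    t_max_ms = t_max_ms, n_t = as.integer(n_t),
    x_breaks = seq(x_min, x_max, length.out = n_x + 1),
    t_bin_ms = t_max_ms / n_t
  ), class = "occupancy_grid")
}

#' @export
print.temporal_grid <- function(x, ...) {
  cat(sprintf("Temporal grid: %g ms bins, %d display bins (%g ms shown)\n",
              x$bin_ms, x$display_bins, x$bin_ms * x$display_bins))
  invisible(x)
}

#' @export
print.stsa_grid <- function(x, ...) {
  cat(sprintf(
    "StSA grid: %d spatial thresholds x %g m (total %g m), %g ms time bins, %d x %d = %d display cells\n",
    x$n_spatial, x$spatial_bin_m, x$total_distance_m, x$temporal$bin_ms,
    x$n_spatial, x$temporal$display_bins,
    x$n_spatial * x$temporal$display_bins))
  invisible(x)
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf(
    "Occupancy grid: %d spatial bins over [%g, %g] m x %d temporal bins over (0, %g] ms (%d cells)\n",
    x$n_x, x$x_min, x$x_max, x$n_t, x$t_max_ms, x$n_x * x$n_t))
  invisible(x)
}
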