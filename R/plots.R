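#' Plot discrete-time survival curves
#'
#' Three stacked panels — hazard h(t), survivor S(t), conditional accuracy
#' ca(t) — over the display window. Bins past the 5\%-of-trials point are
#' greyed (estimates are unchanged underneath), the interpolated median RT
#' is drawn as a dotted vertical line, and ca gaps (bins without events) are
#' left as breaks rather than zeros.
#'
#' @param x A \code{"survival_curves"} object.
#' @param which Panels to draw, subset of \code{c("h", "S", "ca")}.
#' @param ... Passed to \code{plot}.
#' @return Invisibly, \code{x}.
#' @export
plot.survival_curves <- function(x, which = c("h", "S", "ca"), ...) {
  cc <- x$curves[x$curves$bin <= x$grid$display_bins, , drop = FALSE]
  t <- cc$t_upper_ms
  op <- graphics::par(mfrow = c(length(which), 1),
                      mar = c(3.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  mask_t <- if (!is.na(x$mask_from_bin)) x$mask_from_bin * x$grid$bin_ms else NA
  shade <- function(ylim) {
    if (!is.na(mask_t))
      graphics::rect(mask_t, ylim[1] - 1, max(t) + x$grid$bin_ms,
                     ylim[2] + 1, col = "grey88", border = NA)
  }
  for (panel in which) {
    y <- cc[[panel]]
    ylab <- switch(panel, h = "h(t)", S = "S(t)", ca = "ca(t)")
    graphics::plot(t, y, type = "n", ylim = c(0, 1), xlab = "time (ms)",
                   ylab = ylab, ...)
    if (panel != "S") shade(c(0, 1))
    graphics::lines(t, y, type = "s")
    if (panel == "ca")
      graphics::points(t[!is.na(y)], y[!is.na(y)], pch = 16, cex = 0.4)
    if (!is.na(x$median_rt_ms))
      graphics::abline(v = x$median_rt_ms, lty = 3)
    graphics::box()
  }
  invisible(x)
}

#' Heat-map plot of spatiotemporal maps
#'
#' Hazard or conditional accuracy over the display window, spatial
#' thresholds on the vertical axis (increasing upward), time on the
#' horizontal. Undefined CA cells are drawn as background, not zero. Scaled
#' hazard maps share the [0, 1] color range across conditions by
#' construction.
#'
#' @param x An \code{"stsa_maps"} object.
#' @param which \code{"H"} or \code{"CA"}.
#' @param col Color ramp.
#' @param ... Passed to \code{image}.
#' @return Invisibly, \code{x}.
#' @export
plot.stsa_maps <- function(x, which = c("H", "CA"),
                           col = grDevices::hcl.colors(64, "YlOrRd",
                                                       rev = TRUE), ...) {
  which <- match.arg(which)
  db <- x$grid$temporal$display_bins
  m <- x[[which]][, seq_len(min(db, ncol(x[[which]]))), drop = FALSE]
  tvals <- seq_len(ncol(m)) * x$grid$temporal$bin_ms
  svals <- x$grid$thresholds_m
  zlim <- if (which == "H" && !is.na(x$scale)) c(0, 1) else
    range(m, na.rm = TRUE, finite = TRUE)
  if (!all(is.finite(zlim))) zlim <- c(0, 1)
  graphics::image(tvals, svals, t(m), col = col, zlim = zlim,
                  xlab = "time (ms)", ylab = "spatial threshold (m)",
                  main = which, useRaster = TRUE, ...)
  invisible(x)
}

#' Heat-map plot of occupancy counts
#'
#' Log-view occupancy by default (cellwise log10(count + 1)), spatial bins
#' on the vertical axis.
#'
#' @param x An \code{"stsa_occupancy"} object.
#' @param log Use the log view (default TRUE).
#' @param col Color ramp.
#' @param ... Passed to \code{image}.
#' @return Invisibly, \code{x}.
#' @export
plot.stsa_occupancy <- function(x, log = TRUE,
                                col = grDevices::hcl.colors(64, "viridis"),
                                ...) {
  m <- if (log) log_view(x) else x$counts
  g <- x$grid
  xs <- g$x_breaks[-1] - diff(g$x_breaks) / 2
  ts <- (seq_len(g$n_t) - 0.5) * g$t_bin_ms
  graphics::image(ts, xs, t(m), col = col, xlab = "time (ms)",
                  ylab = "position (m)", useRaster = TRUE, ...)
  invisible(x)
}

#' Plot an averaged trajectory
#'
#' Mean signed position over time with the number of contributing trials as
#' a secondary trace; the mean thins out where recordings have ended.
#'
#' @param avg data.frame from \code{\link{average_trajectories}}.
#' @param ... Passed to \code{plot}.
#' @return Invisibly, \code{avg}.
#' @export
plot_average_trajectory <- function(avg, ...) {
  graphics::plot(avg$t_ms, avg$mean_x_m, type = "l",
                 xlab = "time (ms)", ylab = "mean position (m)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(avg)
}

#' Write a map matrix with its grid sidecar
#'
#' CSV twin of every heat-map figure: rows are spatial bins bottom-up,
#' columns are time bins; a JSON sidecar records the grid geometry and any
#' shared hazard scaling constant, so downstream checks never read pixels.
#'
#' @param maps An \code{"stsa_maps"} object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_maps <- function(maps, dir, prefix = "stsa") {
  stopifnot(inherits(maps, "stsa_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("H", "CA", "n_events", "n_at_risk")) {
    p <- file.path(dir, sprintf("%s_%s.csv", prefix, nm))
    utils::write.table(maps[[nm]], p, sep = ",", row.names = FALSE,
                       col.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  side <- file.path(dir, sprintf("%s_grid.json", prefix))
  jsonlite::write_json(list(
    n_spatial = maps$grid$n_spatial,
    spatial_bin_m = maps$grid$spatial_bin_m,
    total_distance_m = maps$grid$total_distance_m,
    bin_ms = maps$grid$temporal$bin_ms,
    display_bins = maps$grid$temporal$display_bins,
    n_trials = maps$n_trials,
    hazard_scale = maps$scale), side, auto_unbox = TRUE, digits = NA,
    null = "null", na = "null")
  invisible(c(paths, side))
}

#' Write survival curves as CSV
#'
#' One row per bin with the condition label, plus the median RT and masking
#' bin in the returned summary attributes; the tabular twin of the survival
#' panels.
#'
#' @param curves_list Named list from \code{\link{survival_by}} (or a single
#'   \code{"survival_curves"}).
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_curves <- function(curves_list, path) {
  if (inherits(curves_list, "survival_curves"))
    curves_list <- list(all = curves_list)
  rows <- lapply(names(curves_list), function(nm) {
    sc <- curves_list[[nm]]
    cbind(data.frame(condition = nm), sc$curves,
          median_rt_ms = sc$median_rt_ms, mask_from_bin = sc$mask_from_bin)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
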