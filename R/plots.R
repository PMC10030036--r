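#' Plot a recurrence matrix
#'
#' Recurrent pairs are drawn in red on white, time running left-to-right and
#' bottom-to-top, matching the conventional rendering of recurrence plots.
#'
#' @param R a `recurrence_matrix` or 0/1 matrix
#' @param file optional PNG path; when given the plot is written there
#' @param ... passed to [graphics::image()]
#' @export
plot_recurrence <- function(R, file = NULL, ...) {
  M <- .rp_matrix(R)
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::image(seq_len(ncol(M)), seq_len(nrow(M)), t(M),
                  col = c("white", "#c0392b"), xlab = "frame i",
                  ylab = "frame j", useRaster = TRUE, ...)
  invisible(NULL)
}

#' Plot a ternary trajectory of shade composition
#'
#' @param traj a `ternary_trajectory`
#' @param file optional PNG path
#' @export
plot_ternary <- function(traj, file = NULL) {
  stopifnot(inherits(traj, "ternary_trajectory"))
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 550)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, sqrt(3) / 2), asp = 1,
                 axes = FALSE, xlab = "", ylab = "")
  graphics::polygon(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2))
  graphics::text(c(-0.03, 1.03, 0.5), c(0, 0, sqrt(3) / 2 + 0.04),
                 c("dark", "medium", "light"))
  graphics::lines(traj$xy[, 1], traj$xy[, 2], col = "grey40")
  graphics::points(traj$xy[, 1], traj$xy[, 2], pch = 16, cex = 0.4,
                   col = "grey55")
  if (!is.null(traj$convergence_center)) {
    cc <- traj$convergence_center
    graphics::points((cc[2] + 0.5 * cc[3]) / 100, sqrt(3) / 2 * cc[3] / 100,
                     pch = 4, col = "red", cex = 1.5, lwd = 2)
  }
  invisible(NULL)
}

#' Plot smoothed dominant-color percentages over time
#'
#' @param series a `dominant_color_series`
#' @param segmentation optional `stage_segmentation`; boundaries drawn as
#'   dashed vertical lines
#' @param file optional PNG path
#' @export
plot_percentages <- function(series, segmentation = NULL, file = NULL) {
  stopifnot(inherits(series, "dominant_color_series"))
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 450)
    on.exit(grDevices::dev.off())
  }
  cols <- c(dark = "#2d5016", medium = "#c0392b", light = "#d4a017")
  graphics::matplot(series$days, series$percentages, type = "l", lty = 1,
                    lwd = 2, col = cols, xlab = "day", ylab = "share (%)")
  graphics::legend("topright", legend = names(cols), col = cols, lty = 1,
                   lwd = 2, bty = "n")
  if (!is.null(segmentation))
    graphics::abline(v = segmentation$boundaries, lty = 2, col = "grey50")
  invisible(NULL)
}
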