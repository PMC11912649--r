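# Base-graphics renderers for the two graphical performance measures.

#' Plot a count-calibration curve
#'
#' Observed counts on the x-axis, predicted on the y-axis; raw points in
#' grey, the smoothed curve with its 95% pointwise band, and the identity
#' line of perfect calibration.
#'
#' @param x A `calibration_curve`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.calibration_curve <- function(x, ...) {
  rng <- range(c(x$points$observed, x$points$predicted,
                 x$lower, x$upper), na.rm = TRUE)
  graphics::plot(x$points$observed, x$points$predicted, col = "grey70",
                 pch = 16, cex = 0.5, xlim = rng, ylim = rng,
                 xlab = "Observed event count",
                 ylab = "Predicted event count",
                 main = if (!is.null(x$model)) x$model else "", ...)
  ok <- is.finite(x$fitted)
  graphics::polygon(c(x$grid[ok], rev(x$grid[ok])),
                    c(x$lower[ok], rev(x$upper[ok])),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(x$grid[ok], x$fitted[ok], col = "steelblue", lwd = 2)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Plot Bland-Altman agreement data
#'
#' Difference (predicted minus observed) against the pairwise mean, with
#' the mean difference (solid) and the 1.96-SD limits of agreement
#' (dotted).  A suppression advisory, when present, is shown as a
#' subtitle.
#'
#' @param x A `bland_altman` object.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$mean, x$difference, pch = 16, cex = 0.6, col = "grey40",
                 xlab = "Mean of predicted and observed count",
                 ylab = "Predicted - observed count",
                 main = if (!is.null(x$model)) x$model else "",
                 sub = if (isTRUE(x$suppressed)) x$advisory else NULL, ...)
  graphics::abline(h = x$mean_difference, lwd = 2)
  graphics::abline(h = c(x$lower_limit, x$upper_limit), lty = 3)
  invisible(x)
}
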