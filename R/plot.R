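#' Estimation plot of the paired dominance-duration difference
#'
#' Two-panel layout in the estimation-graphics style: per-subject
#' condition means connected by lines on top, the bootstrap distribution
#' of the paired difference (with its CI and point estimate) below.
#'
#' @param x A `paired_estimate` from [paired_bootstrap()].
#' @param ... Unused.
#' @return `x`, invisibly. Draws on the current graphics device.
#' @export
plot.paired_estimate <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  ps <- x$per_subject
  wide <- stats::reshape(ps[c("subject", "condition", "mean_duration")],
                         idvar = "subject", timevar = "condition",
                         direction = "wide")
  ylim <- range(wide$mean_duration.systole, wide$mean_duration.diastole)
  graphics::plot(NA, xlim = c(0.75, 2.25), ylim = ylim, xaxt = "n",
                 xlab = "", ylab = "mean dominance duration (s)",
                 main = "per-subject condition means")
  graphics::axis(1, at = 1:2, labels = c("systole", "diastole"))
  for (i in seq_len(nrow(wide)))
    graphics::lines(1:2, c(wide$mean_duration.systole[i],
                           wide$mean_duration.diastole[i]),
                    col = grDevices::adjustcolor(i, alpha.f = 0.6))
  d <- stats::density(x$boot_replicates)
  graphics::plot(d, main = "bootstrap paired differences",
                 xlab = "systole - diastole (s)")
  graphics::abline(v = 0, lty = 3)
  graphics::segments(x$ci_low, 0, x$ci_high, 0, lwd = 3)
  graphics::points(x$mean_diff, 0, pch = 19)
  invisible(x)
}
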