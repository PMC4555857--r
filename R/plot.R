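#' Plot an angular correlation curve
#'
#' @param x A [correlation_curve()].
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.correlation_curve <- function(x, ...) {
  graphics::plot(x$grid$angles, x$values, type = "l",
                 xlab = "angle (deg)", ylab = "normalized correlation",
                 ylim = c(0, 1), ...)
  graphics::abline(v = x$peak_angle, lty = 3)
  invisible(x)
}

#' Plot accuracy and ambiguity profiles
#'
#' Two panels: peak width (degrees) and PSLR (dB) against report angle.
#'
#' @param x A [metrics_profile()] result.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.localization_metrics <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  ok <- x$pw_flag == "ok"
  graphics::plot(x$angle_deg[ok], x$peak_width_deg[ok], type = "l",
                 xlab = "angle (deg)", ylab = "peak width (deg)", ...)
  ok <- x$pslr_flag == "ok"
  graphics::plot(x$angle_deg[ok], x$pslr_db[ok], type = "l",
                 xlab = "angle (deg)", ylab = "PSLR (dB)", ...)
  invisible(x)
}

#' Plot CRLB (and optionally Monte Carlo RMSE) against angle
#'
#' @param x A [crlb_curve()].
#' @param mc Optional [mc_rmse()] result to overlay (points).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.crlb_curve <- function(x, mc = NULL, ...) {
  fin <- is.finite(x$bound_deg)
  graphics::plot(x$angle_deg[fin], x$bound_deg[fin], type = "l", log = "y",
                 xlab = "angle (deg)", ylab = "angular error (deg)", ...)
  if (!is.null(mc)) {
    for (s in unique(mc$snr_db)) {
      sel <- mc$snr_db == s
      graphics::points(mc$angle_deg[sel], mc$rmse_deg[sel], pch = 1)
    }
  }
  invisible(x)
}

#' Plot a beam table as per-band directivity curves
#'
#' @param x An [angle_spectrum_table()].
#' @param bands_hz Frequencies (Hz) of the bands to draw (nearest selected
#'   band is used); default four bands spanning the selection.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.angle_spectrum_table <- function(x, bands_hz = NULL, ...) {
  fsel <- active_bands(x$bands)
  if (is.null(bands_hz)) {
    bands_hz <- stats::quantile(fsel, c(0.05, 0.35, 0.65, 0.95), names = FALSE)
  }
  idx <- vapply(bands_hz, function(f) which.min(abs(fsel - f)), integer(1))
  V <- x$values[, idx, drop = FALSE]
  V <- sweep(V, 2, apply(V, 2, max), "/")
  graphics::matplot(x$grid$angles, 20 * log10(pmax(V, 1e-6)), type = "l",
                    lty = 1, xlab = "angle (deg)",
                    ylab = "relative level (dB)", ...)
  graphics::legend("topright", legend = sprintf("%.0f kHz", fsel[idx] / 1e3),
                   lty = 1, col = seq_along(idx), bty = "n")
  invisible(x)
}
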