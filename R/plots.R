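#' Plot an equilibrium fit
#'
#' Binned dimeric fractions with standard-error bars against total receptor
#' concentration (log axis), overlaid with the fitted mass-action curve.
#'
#' @param x An `EquilibriumFit`.
#' @param n_bins Number of display bins.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.EquilibriumFit <- function(x, n_bins = 10L, ...) {
  b <- bin_dimeric_fractions(x$data, x, n_bins = n_bins)
  Tg <- exp(seq(log(min(x$data$T)), log(max(x$data$T)), length.out = 200))
  graphics::plot(b$bin_mid, b$mean_f_D, log = "x", ylim = c(0, 1),
                 xlab = "total receptor concentration (receptors/um^2)",
                 ylab = "dimeric fraction", pch = 19, ...)
  ok <- is.finite(b$sem)
  graphics::arrows(b$bin_mid[ok], b$mean_f_D[ok] - b$sem[ok],
                   b$bin_mid[ok], b$mean_f_D[ok] + b$sem[ok],
                   angle = 90, code = 3, length = 0.03)
  graphics::lines(Tg, dimeric_fraction(Tg, x$K), col = "red3", lwd = 2)
  invisible(x)
}

#' Plot a constitutive-dimer Intrinsic FRET histogram
#'
#' Per-vesicle Intrinsic FRET histogram with the fitted Gaussian overlaid.
#'
#' @param x A `ConstitutiveFit`.
#' @param ... Passed to [graphics::plot()] via `hist`.
#' @return `x`, invisibly.
#' @export
plot.ConstitutiveFit <- function(x, ...) {
  graphics::hist(x$per_vesicle_E_intrinsic, breaks = x$breaks,
                 xlab = "Intrinsic FRET", main = "", ...)
  xs <- seq(min(x$breaks), max(x$breaks), length.out = 200)
  A <- max(x$counts)
  graphics::lines(xs, A * exp(-(xs - x$gaussian_center)^2 /
                                (2 * x$gaussian_sigma^2)),
                  col = "red3", lwd = 2)
  graphics::abline(v = x$gaussian_center, lty = 2)
  invisible(x)
}

#' Plot a proximity-FRET curve
#'
#' The tabulated stochastic-FRET background versus acceptor density, with
#' Monte-Carlo error bars on the raw simulated points.
#'
#' @param x A `ProximityModel`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ProximityModel <- function(x, ...) {
  graphics::plot(x$density_grid, x$E_prox_curve, type = "l", lwd = 2,
                 xlab = "acceptor density (receptors/um^2)",
                 ylab = "proximity FRET", ...)
  graphics::points(x$density_grid, x$E_prox_raw, pch = 1)
  ok <- is.finite(x$mc_se) & x$mc_se > 0
  graphics::arrows(x$density_grid[ok], x$E_prox_raw[ok] - x$mc_se[ok],
                   x$density_grid[ok], x$E_prox_raw[ok] + x$mc_se[ok],
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}
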