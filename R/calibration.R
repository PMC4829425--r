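#' Calibration constants for three-channel QI-FRET imaging
#'
#' Bundles the five calibration constants that convert raw channel intensities
#' into receptor surface concentrations and FRET efficiencies:
#' `i_D` and `i_A`, the donor and acceptor intensities per unit surface
#' concentration (a.u. per receptor um^-2); `beta_D` and `beta_A`, the
#' bleed-through coefficients of donor emission and directly excited acceptor
#' emission into the FRET channel; and `G_F`, the gauge factor converting
#' sensitized acceptor emission into the equivalent lost donor intensity.
#'
#' @param i_D Donor scale factor, a.u. per receptor um^-2. Must be > 0.
#' @param i_A Acceptor scale factor, a.u. per receptor um^-2. Must be > 0.
#' @param beta_D Donor bleed-through coefficient, in `[0, 1)`.
#' @param beta_A Acceptor bleed-through coefficient, in `[0, 1)`.
#' @param G_F Gauge factor, dimensionless, > 0.
#' @return An object of class `CalibrationSet`.
#' @seealso [calibrate_scale_factors()], [calibrate_bleedthrough()],
#'   [calibrate_gauge_factor()], [calibrate()]
#' @export
#' @examples
#' calibration_set(i_D = 50, i_A = 50, beta_D = 0.3, beta_A = 0.1, G_F = 2)
calibration_set <- function(i_D, i_A, beta_D, beta_A, G_F) {
  vals <- c(i_D = i_D, i_A = i_A, beta_D = beta_D, beta_A = beta_A, G_F = G_F)
  if (any(!is.finite(vals)))
    stop("all calibration constants must be finite", call. = FALSE)
  if (i_D <= 0 || i_A <= 0)
    stop("scale factors i_D and i_A must be positive", call. = FALSE)
  if (beta_D < 0 || beta_D >= 1 || beta_A < 0 || beta_A >= 1)
    stop("bleed-through coefficients must lie in [0, 1)", call. = FALSE)
  if (G_F <= 0)
    stop("gauge factor G_F must be positive", call. = FALSE)
  structure(list(i_D = i_D, i_A = i_A, beta_D = beta_D, beta_A = beta_A,
                 G_F = G_F),
            class = "CalibrationSet")
}

#' @export
print.CalibrationSet <- function(x, ...) {
  cat("QI-FRET calibration constants\n")
  cat(sprintf("  i_D    = %.6g a.u. per receptor/um^2\n", x$i_D))
  cat(sprintf("  i_A    = %.6g a.u. per receptor/um^2\n", x$i_A))
  cat(sprintf("  beta_D = %.6g\n", x$beta_D))
  cat(sprintf("  beta_A = %.6g\n", x$beta_A))
  cat(sprintf("  G_F    = %.6g\n", x$G_F))
  invisible(x)
}

# Through-origin least-squares slope: minimizes sum (y - b x)^2, b = Sxy/Sxx.
# Zero-intercept is physical here: zero concentration gives zero signal.
slope_through_origin <- function(x, y, what = "slope") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L)
    stop(sprintf("%s calibration needs at least 2 points, got %d",
                 what, length(x)), call. = FALSE)
  sxx <- sum(x^2)
  if (sxx == 0)
    stop(sprintf("%s calibration is degenerate: all predictor values are zero",
                 what), call. = FALSE)
  sum(x * y) / sxx
}

#' Derive channel scale factors from solution standards
#'
#' Fits through-origin least-squares lines of channel intensity versus known
#' fluorophore concentration for donor-only and acceptor-only solution
#' standards, returning the per-unit-concentration scale factors `i_D` and
#' `i_A`.
#'
#' @param donor_standards Data frame with columns `concentration` and `I_D`
#'   for donor-only solutions of known concentration.
#' @param acceptor_standards Data frame with columns `concentration` and `I_A`
#'   for acceptor-only solutions.
#' @return A list with components `i_D` and `i_A` (both > 0).
#' @export
calibrate_scale_factors <- function(donor_standards, acceptor_standards) {
  need <- function(df, col, tab) {
    if (!col %in% names(df))
      stop(sprintf("%s standards table lacks column '%s'", tab, col),
           call. = FALSE)
    df[[col]]
  }
  cd <- need(donor_standards, "concentration", "donor")
  id <- need(donor_standards, "I_D", "donor")
  ca <- need(acceptor_standards, "concentration", "acceptor")
  ia <- need(acceptor_standards, "I_A", "acceptor")
  if (any(cd < 0) || any(ca < 0))
    stop("standard concentrations must be non-negative", call. = FALSE)
  if (any(id < 0) || any(ia < 0))
    stop("standard intensities must be non-negative", call. = FALSE)
  if (length(unique(cd[cd > 0])) < 2L || length(unique(ca[ca > 0])) < 2L)
    stop("need at least 2 distinct non-zero concentrations per fluorophore",
         call. = FALSE)
  i_D <- slope_through_origin(cd, id, "donor scale-factor")
  i_A <- slope_through_origin(ca, ia, "acceptor scale-factor")
  if (i_D <= 0 || i_A <= 0)
    stop(sprintf(paste0("calibration failure: non-positive scale factor ",
                        "(i_D = %.4g, i_A = %.4g)"), i_D, i_A), call. = FALSE)
  list(i_D = i_D, i_A = i_A)
}

#' Derive bleed-through coefficients from single-fluorophore records
#'
#' The FRET channel receives a fraction `beta_D` of the donor-channel signal
#' (donor emission tail) and a fraction `beta_A` of the acceptor-channel signal
#' (direct acceptor excitation). Both are estimated as through-origin slopes of
#' `I_FRET` against the respective channel over single-fluorophore records.
#'
#' @param donor_only Data frame with columns `I_D`, `I_A`, `I_FRET` from
#'   donor-only samples (`I_A` expected ~ 0).
#' @param acceptor_only Data frame with the same columns from acceptor-only
#'   samples (`I_D` expected ~ 0).
#' @return A list with components `beta_D` and `beta_A`, both in `[0, 1)`.
#' @export
calibrate_bleedthrough <- function(donor_only, acceptor_only) {
  if (any(donor_only$I_A > 0.05 * pmax(donor_only$I_D, 1e-12)))
    warning("donor-only records show appreciable acceptor-channel signal")
  if (any(acceptor_only$I_D > 0.05 * pmax(acceptor_only$I_A, 1e-12)))
    warning("acceptor-only records show appreciable donor-channel signal")
  beta_D <- slope_through_origin(donor_only$I_D, donor_only$I_FRET,
                                 "donor bleed-through")
  beta_A <- slope_through_origin(acceptor_only$I_A, acceptor_only$I_FRET,
                                 "acceptor bleed-through")
  for (b in c(beta_D = beta_D, beta_A = beta_A)) {
    if (b < 0 || b >= 1)
      stop(sprintf("calibration failure: bleed-through slope %.4g outside [0, 1)",
                   b), call. = FALSE)
  }
  list(beta_D = beta_D, beta_A = beta_A)
}

#' Derive the gauge factor from a linked donor-acceptor standard
#'
#' For a construct in which every donor is covalently linked to exactly one
#' acceptor with known FRET efficiency `E`, the reconstructed donor intensity
#' is `I_D / (1 - E)`, so the lost donor intensity `I_D * E / (1 - E)` must
#' equal `G_F * I_SEN`. `G_F` is recovered as the through-origin slope of the
#' lost donor intensity against the sensitized emission across records.
#'
#' @param linked_records Data frame with columns `I_D`, `I_A`, `I_FRET` from
#'   the linked-construct sample.
#' @param beta_D,beta_A Bleed-through coefficients (see
#'   [calibrate_bleedthrough()]).
#' @param known_efficiency FRET efficiency of the linked construct, in (0, 1).
#' @return The gauge factor `G_F` (> 0).
#' @export
calibrate_gauge_factor <- function(linked_records, beta_D, beta_A,
                                   known_efficiency) {
  if (!is.finite(known_efficiency) ||
      known_efficiency <= 0 || known_efficiency >= 1)
    stop("known linked-construct efficiency must lie strictly in (0, 1)",
         call. = FALSE)
  I_SEN <- linked_records$I_FRET - beta_A * linked_records$I_A -
    beta_D * linked_records$I_D
  if (all(abs(I_SEN) < .Machine$double.eps^0.5) || sum(I_SEN^2) == 0)
    stop("calibration failure: no sensitized emission in linked-construct records",
         call. = FALSE)
  lost_donor <- linked_records$I_D * known_efficiency / (1 - known_efficiency)
  G_F <- slope_through_origin(I_SEN, lost_donor, "gauge-factor")
  if (!is.finite(G_F) || G_F <= 0)
    stop(sprintf("calibration failure: non-positive gauge factor (%.4g)", G_F),
         call. = FALSE)
  G_F
}

#' Full calibration from standards
#'
#' Convenience wrapper running [calibrate_scale_factors()],
#' [calibrate_bleedthrough()] and [calibrate_gauge_factor()] on a set of
#' standards tables and assembling a complete [calibration_set()].
#'
#' @param donor_standards,acceptor_standards Concentration standards, data
#'   frames with `concentration` and the three channel columns.
#' @param linked_records Linked donor-acceptor construct records.
#' @param known_efficiency FRET efficiency of the linked construct.
#' @return A `CalibrationSet`.
#' @export
calibrate <- function(donor_standards, acceptor_standards, linked_records,
                      known_efficiency) {
  sf <- calibrate_scale_factors(donor_standards, acceptor_standards)
  bt <- calibrate_bleedthrough(donor_standards, acceptor_standards)
  G_F <- calibrate_gauge_factor(linked_records, bt$beta_D, bt$beta_A,
                                known_efficiency)
  calibration_set(i_D = sf$i_D, i_A = sf$i_A,
                  beta_D = bt$beta_D, beta_A = bt$beta_A, G_F = G_F)
}

#' Read or write a calibration file
#'
#' Calibration constants are stored as a small YAML mapping so they can be
#' reused across imaging sessions.
#'
#' @param cal A `CalibrationSet`.
#' @param path File path.
#' @return `read_calibration` returns a `CalibrationSet`; `write_calibration`
#'   returns `path` invisibly.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "CalibrationSet"))
  yaml::write_yaml(unclass(cal), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- yaml::read_yaml(path)
  calibration_set(i_D = x$i_D, i_A = x$i_A, beta_D = x$beta_D,
                  beta_A = x$beta_A, G_F = x$G_F)
}
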