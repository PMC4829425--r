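#' Configuration for the synthetic single-vesicle generator
#'
#' Describes the ground truth and noise model of a simulated single-vesicle
#' FRET experiment. Defaults mirror a typical measurement campaign: total
#' receptor concentrations log-uniform over 1-1000 receptors um^-2 (about
#' three decades, as transient transfection produces), acceptor fractions
#' uniform on 0.2-0.8, 300 vesicles, additive Gaussian noise of 0.05 on the
#' per-vesicle efficiency plus 2% multiplicative lognormal noise on the raw
#' intensities.
#'
#' @param K_diss True dissociation constant (receptors um^-2); ignored when
#'   `constitutive = TRUE`.
#' @param E_intrinsic True Intrinsic FRET, in (0, 1).
#' @param constitutive If `TRUE`, every receptor is dimeric regardless of
#'   concentration (`f_D = 1`).
#' @param T_bounds Log-uniform bounds for total concentration
#'   (receptors um^-2).
#' @param xa_bounds Uniform bounds for the acceptor fraction.
#' @param n_vesicles Number of vesicles to generate.
#' @param sigma_E SD of additive Gaussian noise on the per-vesicle efficiency.
#' @param sigma_rel SD of multiplicative lognormal noise on raw intensities.
#' @param proximity_model Optional [build_proximity_curve()] model adding the
#'   stochastic-FRET background at each vesicle's acceptor density.
#' @param calibration Ground-truth [calibration_set()] used to invert the
#'   quantification equations into raw intensities.
#' @param seed Integer seed (mandatory; generators never touch global state
#'   beyond `set.seed`).
#' @return An object of class `SyntheticConfig`.
#' @export
synthetic_config <- function(K_diss = 35, E_intrinsic = 0.82,
                             constitutive = FALSE,
                             T_bounds = c(1, 1000), xa_bounds = c(0.2, 0.8),
                             n_vesicles = 300L, sigma_E = 0.05,
                             sigma_rel = 0.02, proximity_model = NULL,
                             calibration = calibration_set(50, 50, 0.30,
                                                           0.10, 2.0),
                             seed = 1L) {
  if (!constitutive && (!is.finite(K_diss) || K_diss <= 0))
    stop("K_diss must be finite and positive (or set constitutive = TRUE)",
         call. = FALSE)
  if (!is.finite(E_intrinsic) || E_intrinsic <= 0 || E_intrinsic >= 1)
    stop("E_intrinsic must lie in (0, 1)", call. = FALSE)
  if (length(T_bounds) != 2L || T_bounds[1] <= 0 || diff(T_bounds) < 0)
    stop("T_bounds must be positive and ordered", call. = FALSE)
  if (length(xa_bounds) != 2L || xa_bounds[1] < 0 || xa_bounds[2] > 1 ||
      diff(xa_bounds) < 0)
    stop("xa_bounds must be ordered within [0, 1]", call. = FALSE)
  if (n_vesicles < 1L) stop("n_vesicles must be >= 1", call. = FALSE)
  if (sigma_E < 0 || sigma_rel < 0)
    stop("noise parameters must be >= 0", call. = FALSE)
  if (!is.null(proximity_model) && !inherits(proximity_model,
                                             "ProximityModel"))
    stop("proximity_model must be a ProximityModel or NULL", call. = FALSE)
  stopifnot(inherits(calibration, "CalibrationSet"))
  structure(list(K_diss = K_diss, E_intrinsic = E_intrinsic,
                 constitutive = constitutive, T_bounds = T_bounds,
                 xa_bounds = xa_bounds, n_vesicles = as.integer(n_vesicles),
                 sigma_E = sigma_E, sigma_rel = sigma_rel,
                 proximity_model = proximity_model,
                 calibration = calibration, seed = as.integer(seed)),
            class = "SyntheticConfig")
}

# Invert the quantification equations: from (C_D, C_A, E) and calibration
# truth to the three raw channel intensities.
invert_quantification <- function(C_D, C_A, E, cal) {
  I_A <- C_A * cal$i_A
  I_D_corr <- C_D * cal$i_D
  I_D <- (1 - E) * I_D_corr
  I_SEN <- (I_D_corr - I_D) / cal$G_F
  I_FRET <- I_SEN + cal$beta_A * I_A + cal$beta_D * I_D
  data.frame(I_D = I_D, I_A = I_A, I_FRET = I_FRET)
}

# Additive Gaussian noise on an efficiency, resampled (not clipped) until the
# result lies in [0, 1) so the generated ensemble never contains impossible
# efficiencies.
resample_efficiency_noise <- function(E_true, sigma) {
  if (sigma == 0) return(E_true)
  E <- E_true + stats::rnorm(length(E_true), sd = sigma)
  bad <- which(E < 0 | E >= 1)
  guard <- 0L
  while (length(bad)) {
    E[bad] <- E_true[bad] + stats::rnorm(length(bad), sd = sigma)
    bad <- bad[E[bad] < 0 | E[bad] >= 1]
    guard <- guard + 1L
    if (guard > 1000L)
      stop("efficiency noise resampling failed to converge", call. = FALSE)
  }
  E
}

generate_vesicles_impl <- function(config) {
  set.seed(config$seed)
  n <- config$n_vesicles
  Tt <- exp(stats::runif(n, log(config$T_bounds[1]), log(config$T_bounds[2])))
  x_A <- stats::runif(n, config$xa_bounds[1], config$xa_bounds[2])
  f_D <- if (config$constitutive) rep(1, n) else
    dimeric_fraction(Tt, 1 / config$K_diss)
  C_A <- x_A * Tt
  C_D <- (1 - x_A) * Tt
  E_D_true <- f_D * x_A * config$E_intrinsic
  E_prox <- if (is.null(config$proximity_model)) rep(0, n) else
    eval_proximity(config$proximity_model, C_A)$E_prox
  E_true <- pmin(E_D_true + E_prox, 1 - 1e-9)
  E_noisy <- resample_efficiency_noise(E_true, config$sigma_E)

  clean <- invert_quantification(C_D, C_A, E_true, config$calibration)
  noisy <- invert_quantification(C_D, C_A, E_noisy, config$calibration)
  if (config$sigma_rel > 0) {
    s <- config$sigma_rel
    for (col in names(noisy))
      noisy[[col]] <- noisy[[col]] *
        stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
  }
  ids <- seq_len(n)
  list(
    intensities = cbind(data.frame(vesicle_id = ids), noisy),
    truth = cbind(data.frame(vesicle_id = ids, T = Tt, x_A = x_A,
                             C_D = C_D, C_A = C_A, f_D = f_D,
                             E_D = E_D_true, E_prox = E_prox, E = E_true),
                  stats::setNames(clean, paste0(names(clean), "_clean"))),
    config = config)
}

#' Generate synthetic single-vesicle records
#'
#' `generate_equilibrium_vesicles` draws, per vesicle, a total concentration
#' (log-uniform) and acceptor fraction (uniform), computes the dimeric
#' fraction from mass action at the configured `K_diss`, forms the corrected
#' efficiency `E_D = f_D * x_A * E_intrinsic`, adds the proximity-FRET
#' background at the vesicle's acceptor density when configured, inverts the
#' quantification equations with the ground-truth calibration to obtain raw
#' channel intensities, and applies the noise model (additive Gaussian on the
#' efficiency, resampled into `[0, 1)`; multiplicative lognormal on the
#' intensities). `generate_constitutive_vesicles` is identical except that
#' the dimeric fraction is 1 for every vesicle.
#'
#' @param config A [synthetic_config()].
#' @return A list with `intensities` (noisy per-vesicle intensity table with
#'   columns `vesicle_id`, `I_D`, `I_A`, `I_FRET`), `truth` (noise-free
#'   ground-truth table, one row per vesicle) and the `config` used.
#' @export
generate_equilibrium_vesicles <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (config$constitutive)
    stop("config has the constitutive flag set; use ",
         "generate_constitutive_vesicles()", call. = FALSE)
  generate_vesicles_impl(config)
}

#' @rdname generate_equilibrium_vesicles
#' @export
generate_constitutive_vesicles <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (!config$constitutive)
    stop("config lacks the constitutive flag; use ",
         "generate_equilibrium_vesicles()", call. = FALSE)
  generate_vesicles_impl(config)
}

#' Generate synthetic calibration standards
#'
#' Emulates the calibration samples of a QI-FRET session: donor-only and
#' acceptor-only solutions of known concentration, and a linked
#' donor-acceptor construct of known FRET efficiency, all consistent with a
#' ground-truth calibration plus optional multiplicative lognormal noise.
#'
#' @param calibration_truth A [calibration_set()] serving as ground truth.
#' @param concentrations Standard concentrations (receptors um^-2 equivalent
#'   units), all > 0.
#' @param linked_efficiency FRET efficiency of the linked construct.
#' @param n_linked Number of linked-construct records.
#' @param noise Relative (lognormal) intensity noise SD; 0 for exact tables.
#' @param seed Integer seed.
#' @return A list with data frames `donor`, `acceptor` (columns
#'   `concentration`, `I_D`, `I_A`, `I_FRET`) and `linked` (channel columns),
#'   plus `linked_efficiency` and the `truth` calibration.
#' @export
generate_calibration_standards <- function(calibration_truth,
                                           concentrations = c(50, 100, 200,
                                                              400, 800),
                                           linked_efficiency = 0.5,
                                           n_linked = 50L, noise = 0,
                                           seed = 1L) {
  stopifnot(inherits(calibration_truth, "CalibrationSet"))
  if (length(concentrations) == 0L || any(concentrations <= 0))
    stop("concentrations must be a non-empty positive vector", call. = FALSE)
  if (linked_efficiency <= 0 || linked_efficiency >= 1)
    stop("linked efficiency must lie in (0, 1)", call. = FALSE)
  set.seed(seed)
  cal <- calibration_truth
  jitter <- function(x) {
    if (noise == 0) x else
      x * stats::rlnorm(length(x), meanlog = -noise^2 / 2, sdlog = noise)
  }
  donor <- data.frame(concentration = concentrations,
                      I_D = jitter(cal$i_D * concentrations),
                      I_A = 0,
                      I_FRET = jitter(cal$beta_D * cal$i_D * concentrations))
  acceptor <- data.frame(concentration = concentrations,
                         I_D = 0,
                         I_A = jitter(cal$i_A * concentrations),
                         I_FRET = jitter(cal$beta_A * cal$i_A *
                                           concentrations))
  Cl <- stats::runif(n_linked, min(concentrations), max(concentrations))
  base <- invert_quantification(C_D = Cl, C_A = Cl,
                                E = rep(linked_efficiency, n_linked), cal)
  linked <- as.data.frame(lapply(base, jitter))
  list(donor = donor, acceptor = acceptor, linked = linked,
       linked_efficiency = linked_efficiency, truth = calibration_truth)
}
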