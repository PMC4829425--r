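#' Configuration for an end-to-end QI-FRET run
#'
#' Collects every input, threshold and seed needed by [run_pipeline()], so a
#' run is a pure function of its configuration.
#'
#' @param intensities Per-vesicle intensity table (data frame) or path to a
#'   tab-separated table with columns `vesicle_id`, `I_D`, `I_A`, `I_FRET`.
#' @param calibration A [calibration_set()], or path to a calibration YAML
#'   file, or `NULL` when `standards` are given.
#' @param standards Optional list with `donor`, `acceptor`, `linked` tables
#'   and `linked_efficiency`, as produced by
#'   [generate_calibration_standards()]; used to derive the calibration when
#'   `calibration` is `NULL`.
#' @param proximity A `ProximityModel`, or path to a stored curve, or `NULL`
#'   to build one from `R0`, `exclusion_radius` and `seed`.
#' @param mode `"auto"` (run the concentration-dependence test and branch),
#'   `"equilibrium"` or `"constitutive"`.
#' @param RT Thermal energy (kcal mol^-1).
#' @param R0 Förster radius (Angstrom).
#' @param exclusion_radius Proximity-model exclusion radius (Angstrom).
#' @param alpha Significance level of the concentration-dependence test.
#' @param xa_bounds Acceptor-fraction window for constitutive estimates.
#' @param sigma_background Background noise SD for [quantify_vesicles()]
#'   (`NULL` = estimate from data).
#' @param output_dir Directory for persisted outputs, or `NULL` to skip
#'   writing.
#' @param seed Integer seed for every stochastic step.
#' @return A list of class `RunConfig`.
#' @export
run_config <- function(intensities, calibration = NULL, standards = NULL,
                       proximity = NULL, mode = c("auto", "equilibrium",
                                                  "constitutive"),
                       RT = 0.596, R0 = 53.1, exclusion_radius = 10,
                       alpha = 0.05, xa_bounds = c(0.05, 0.95),
                       sigma_background = NULL, output_dir = NULL,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(calibration) && is.null(standards))
    stop("provide either a calibration or standards tables", call. = FALSE)
  for (p in Filter(is.character, list(intensities, calibration, proximity)))
    if (!file.exists(p)) stop("input path does not exist: ", p, call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  structure(list(intensities = intensities, calibration = calibration,
                 standards = standards, proximity = proximity, mode = mode,
                 RT = RT, R0 = R0, exclusion_radius = exclusion_radius,
                 alpha = alpha, xa_bounds = xa_bounds,
                 sigma_background = sigma_background,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "RunConfig")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full QI-FRET analysis
#'
#' Executes calibrate, quantify, proximity-correct, mode-select and fit in
#' sequence, returning a report bundle and (optionally) persisting every
#' intermediate table so each summary number can be reproduced from disk.
#' In `"auto"` mode the concentration-dependence test chooses between the
#' equilibrium and constitutive analyses; when the test is marginal (p within
#' a factor of 2 of `alpha` on either side) both analyses are retained, with
#' the test's choice as `fit` and the alternative as `alternative_fit`.
#'
#' @param config A [run_config()].
#' @return A list of class `QIFretReport` with elements `calibration`,
#'   `vesicles` (augmented table), `proximity_model`, `decision`, `mode`,
#'   `fit` (an `EquilibriumFit` or `ConstitutiveFit`), optionally
#'   `alternative_fit` and `binned`, and `summary` (flat named list of the
#'   headline numbers at full precision).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))

  cal <- pipeline_stage("calibrate", {
    if (inherits(config$calibration, "CalibrationSet")) config$calibration
    else if (is.character(config$calibration))
      read_calibration(config$calibration)
    else calibrate(config$standards$donor, config$standards$acceptor,
                   config$standards$linked,
                   config$standards$linked_efficiency)
  })

  tab <- pipeline_stage("quantify", {
    raw <- if (is.character(config$intensities))
      read_vesicle_table(config$intensities) else config$intensities
    quantify_vesicles(raw, cal, sigma_background = config$sigma_background)
  })

  prox <- pipeline_stage("proximity", {
    if (inherits(config$proximity, "ProximityModel")) config$proximity
    else if (is.character(config$proximity))
      read_proximity_curve(config$proximity)
    else build_proximity_curve(
      R0 = config$R0, exclusion_radius = config$exclusion_radius,
      mc_settings = proximity_mc_settings(seed = config$seed))
  })
  tab <- pipeline_stage("correct", correct_fret(tab, prox))

  decision <- pipeline_stage("mode-selection",
    detect_concentration_dependence(tab, alpha = config$alpha))
  mode <- if (config$mode == "auto") {
    if (decision$decision == "undecidable")
      stop("pipeline stage 'mode-selection' failed: concentration ",
           "dependence undecidable (", decision$reason,
           "); force a mode explicitly", call. = FALSE)
    decision$decision
  } else config$mode

  fit_equilibrium <- function()
    fit_monomer_dimer(tab, RT = config$RT, R0 = config$R0)
  fit_constitutive <- function()
    constitutive_intrinsic_fret(tab, xa_bounds = config$xa_bounds,
                                R0 = config$R0)
  fit <- pipeline_stage("fit",
    if (mode == "equilibrium") fit_equilibrium() else fit_constitutive())

  alternative <- NULL
  marginal <- config$mode == "auto" && is.finite(decision$p_value) &&
    decision$p_value > config$alpha / 2 && decision$p_value < config$alpha * 2
  if (marginal)
    alternative <- tryCatch(
      if (mode == "equilibrium") fit_constitutive() else fit_equilibrium(),
      error = function(e) NULL, warning = function(w) NULL)

  binned <- if (inherits(fit, "EquilibriumFit"))
    bin_dimeric_fractions(tab, fit) else NULL

  summary <- if (inherits(fit, "EquilibriumFit")) {
    phys <- dimeric_fraction_at_physiological_density(fit)
    list(mode = mode, n_vesicles = fit$n_vesicles, K_diss = fit$K_diss,
         K_diss_ci67_lo = fit$ci67_K_diss[1],
         K_diss_ci67_hi = fit$ci67_K_diss[2],
         delta_G = fit$delta_G, delta_G_se = fit$se_delta_G,
         E_intrinsic = fit$E_intrinsic, E_intrinsic_se = fit$se_E,
         d = fit$d, converged = fit$converged,
         f_D_at_10 = unname(phys[1]), f_D_at_100 = unname(phys[2]),
         decision_p_value = decision$p_value, seed = config$seed)
  } else {
    list(mode = mode, n_vesicles = fit$n_vesicles,
         E_intrinsic = fit$gaussian_center,
         E_intrinsic_sigma = fit$gaussian_sigma,
         E_intrinsic_sem = fit$sem, d = fit$d,
         decision_p_value = decision$p_value, seed = config$seed)
  }

  report <- structure(list(calibration = cal, vesicles = tab,
                           proximity_model = prox, decision = decision,
                           mode = mode, fit = fit,
                           alternative_fit = alternative, binned = binned,
                           summary = summary, config = config),
                      class = "QIFretReport")
  if (!is.null(config$output_dir)) persist_report(report, config$output_dir)
  report
}

persist_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_calibration(report$calibration, file.path(dir, "calibration.yaml"))
  write_vesicle_table(report$vesicles, file.path(dir, "vesicles.tsv"))
  write_proximity_curve(report$proximity_model,
                        file.path(dir, "proximity_curve.tsv"))
  if (!is.null(report$binned))
    utils::write.table(report$binned, file.path(dir, "binned_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(report$summary, file.path(dir, "summary.yaml"))
  writeLines(utils::capture.output(print(report)),
             file.path(dir, "report.txt"))
  invisible(dir)
}

#' @export
print.QIFretReport <- function(x, ...) {
  cat("QI-FRET pipeline report\n")
  cat(sprintf("  mode: %s (concentration-dependence p = %.3g)\n",
              x$mode, x$decision$p_value))
  print(x$fit)
  if (!is.null(x$alternative_fit)) {
    cat("  marginal decision; alternative analysis retained:\n")
    print(x$alternative_fit)
  }
  invisible(x)
}

# Distance display convention: one decimal below 50 A, nearest integer at
# or above 50 A.
format_distance <- function(d) {
  ifelse(d < 50, sprintf("%.1f", d), sprintf("%.0f", round(d)))
}

#' Format fits as a comparison table
#'
#' Renders one row per construct/condition in the conventional layout:
#' dissociation constant with 67% CI, dimerization free energy with 67% CI,
#' Intrinsic FRET with its uncertainty, and donor-acceptor distance.
#' Constitutive fits print a `100% dimer` marker in place of the equilibrium
#' quantities and report the Intrinsic FRET as center plus or minus the
#' Gaussian width. Free energies are rounded to one decimal; distances to one
#' decimal below 50 Angstrom and to the nearest Angstrom above.
#'
#' @param fits A single fit or list of `EquilibriumFit` / `ConstitutiveFit`
#'   objects.
#' @param labels Optional row labels (construct names).
#' @return A data frame with character columns `construct`, `K_diss`,
#'   `delta_G`, `E_intrinsic`, `d`.
#' @export
report_table1_style <- function(fits, labels = NULL) {
  if (inherits(fits, c("EquilibriumFit", "ConstitutiveFit")))
    fits <- list(fits)
  if (length(fits) < 1L) stop("need at least one fit", call. = FALSE)
  if (is.null(labels)) labels <- paste("construct", seq_along(fits))
  rows <- mapply(function(f, lab) {
    if (inherits(f, "EquilibriumFit")) {
      data.frame(construct = lab,
                 K_diss = sprintf("%.0f (%.0f to %.0f)", f$K_diss,
                                  f$ci67_K_diss[1], f$ci67_K_diss[2]),
                 delta_G = sprintf("%.1f (%.1f to %.1f)", f$delta_G,
                                   f$ci67_delta_G[1], f$ci67_delta_G[2]),
                 E_intrinsic = sprintf("%.2f (%.2f to %.2f)", f$E_intrinsic,
                                       f$ci67_E[1], f$ci67_E[2]),
                 d = format_distance(f$d))
    } else if (inherits(f, "ConstitutiveFit")) {
      data.frame(construct = lab, K_diss = "100% dimer",
                 delta_G = "100% dimer",
                 E_intrinsic = sprintf("%.2f ± %.2f", f$gaussian_center,
                                       f$gaussian_sigma),
                 d = format_distance(f$d))
    } else stop("unsupported fit object of class ", class(f)[1],
                call. = FALSE)
  }, fits, labels, SIMPLIFY = FALSE)
  do.call(rbind, rows)
}
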