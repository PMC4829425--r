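#' Dimeric fraction under a two-dimensional monomer-dimer equilibrium
#'
#' Mass action in the membrane plane with association constant `K`
#' (um^2 receptor^-1) gives, at total receptor concentration `T`
#' (receptors um^-2), the dimeric fraction
#' `f_D = (1/T) * (T - (sqrt(1 + 8 T K) - 1) / (4 K))`.
#' The implementation uses the algebraically identical but numerically stable
#' form `f_D = 1 - 2 / (1 + sqrt(1 + 8 T K))`, which avoids cancellation at
#' small `T K` and gives `f_D(0) = 0` exactly.
#'
#' @param T Total receptor concentration (receptors um^-2), >= 0. Vectorized.
#' @param K Association constant (um^2 receptor^-1), > 0.
#' @return Dimeric fraction in `[0, 1)`.
#' @export
#' @examples
#' dimeric_fraction(100, K = 1 / 35)
dimeric_fraction <- function(T, K) {
  if (!is.finite(K) || K <= 0)
    stop("association constant K must be finite and positive", call. = FALSE)
  if (any(T < 0)) stop("total concentration must be >= 0", call. = FALSE)
  1 - 2 / (1 + sqrt(1 + 8 * T * K))
}

#' Dimerization free energy from the dissociation constant
#'
#' With the standard state of one receptor per nm^2 (10^6 receptors um^-2),
#' `delta_G = -RT * ln(10^6 / K_diss)` in kcal mol^-1. `RT = 0.596` kcal
#' mol^-1 corresponds to T = 300 K.
#'
#' @param K_diss Dissociation constant (receptors um^-2), > 0. Vectorized.
#' @param RT Thermal energy (kcal mol^-1).
#' @return Free energy in kcal mol^-1 (negative for `K_diss < 10^6`).
#' @export
#' @examples
#' dimerization_free_energy(35) # about -6.1 kcal/mol
dimerization_free_energy <- function(K_diss, RT = 0.596) {
  if (any(!is.finite(K_diss)) || any(K_diss <= 0))
    stop("K_diss must be finite and positive", call. = FALSE)
  -RT * log(1e6 / K_diss)
}

#' Free-energy difference between two constructs
#'
#' Positive values mean construct `a` dimerizes less favourably (its dimer is
#' less stable) than construct `b`.
#'
#' @param delta_G_a,delta_G_b Free energies (kcal mol^-1).
#' @return `delta_G_a - delta_G_b`.
#' @export
delta_delta_g <- function(delta_G_a, delta_G_b) {
  stopifnot(is.finite(delta_G_a), is.finite(delta_G_b))
  delta_G_a - delta_G_b
}

#' Convert Intrinsic FRET to donor-acceptor distance and back
#'
#' The Förster relation `E = 1 / (1 + (d/R0)^6)` inverts to
#' `d = R0 * ((1 - E) / E)^(1/6)`. Distances assume free fluorophore rotation
#' (orientation factor not modelled).
#'
#' @param E_intrinsic Intrinsic FRET efficiency, strictly in (0, 1).
#'   Vectorized.
#' @param d Donor-acceptor distance (Angstrom), > 0. Vectorized.
#' @param R0 Förster radius (Angstrom); 53.1 for YFP/mCherry.
#' @return Distance in Angstrom, or efficiency in (0, 1).
#' @export
#' @examples
#' intrinsic_fret_to_distance(0.5) # equals R0
intrinsic_fret_to_distance <- function(E_intrinsic, R0 = 53.1) {
  if (any(!is.finite(E_intrinsic)) ||
      any(E_intrinsic <= 0) || any(E_intrinsic >= 1))
    stop("Intrinsic FRET must lie strictly in (0, 1)", call. = FALSE)
  R0 * ((1 - E_intrinsic) / E_intrinsic)^(1 / 6)
}

#' @rdname intrinsic_fret_to_distance
#' @export
distance_to_intrinsic_fret <- function(d, R0 = 53.1) {
  if (any(!is.finite(d)) || any(d <= 0))
    stop("distance must be finite and positive", call. = FALSE)
  1 / (1 + (d / R0)^6)
}

# Usable records for equilibrium/constitutive analysis: unflagged, with
# finite E_D, x_A strictly inside (0,1) and positive T.
usable_fret_records <- function(records, xa_bounds = c(0, 1)) {
  if (!all(c("E_D", "x_A", "T") %in% names(records)))
    stop("records must carry E_D, x_A and T (run the upstream modules first)",
         call. = FALSE)
  ok <- is_unflagged(records) &
    is.finite(records$E_D) & is.finite(records$x_A) & is.finite(records$T) &
    records$x_A > max(0, xa_bounds[1]) &
    records$x_A < min(1, xa_bounds[2]) &
    records$T > 0
  records[ok, , drop = FALSE]
}

#' Fit the monomer-dimer equilibrium to corrected single-vesicle FRET
#'
#' Minimizes, over the association constant `K` and the Intrinsic FRET
#' `E_intrinsic`, the unweighted sum of squares
#' `sum((E_D/x_A - f_D(T; K) * E_intrinsic)^2)` across usable vesicles.
#' `K` is parameterized as `log K` to enforce positivity; `E_intrinsic` is
#' box-constrained to (0, 1). Standard errors come from the local quadratic
#' approximation at the optimum (Hessian of the sum of squares, residual
#' variance `SSR/(n-2)`); 67% confidence intervals are the estimate plus or
#' minus one standard error, applied on the log scale for `K_diss`. The fit
#' also reports the dimerization free energy (via
#' [dimerization_free_energy()]) and the donor-acceptor distance (via
#' [intrinsic_fret_to_distance()]).
#'
#' @param records Per-vesicle table with `E_D`, `x_A`, `T` (and optionally
#'   `quality_flags`); flagged rows are ignored.
#' @param RT Thermal energy (kcal mol^-1) for the free-energy conversion.
#' @param R0 Förster radius (Angstrom) for the distance conversion.
#' @param min_records Minimum number of usable vesicles (default 10).
#' @return An object of class `EquilibriumFit`.
#' @export
fit_monomer_dimer <- function(records, RT = 0.596, R0 = 53.1,
                              min_records = 10L) {
  rec <- usable_fret_records(records)
  n <- nrow(rec)
  if (n < min_records)
    stop(sprintf("monomer-dimer fit needs >= %d usable records, got %d",
                 min_records, n), call. = FALSE)
  if (length(unique(rec$T)) < 3L)
    stop("monomer-dimer fit not identifiable: needs spread in total ",
         "concentration (got < 3 distinct values); consider the ",
         "constitutive-dimer analysis", call. = FALSE)
  y <- rec$E_D / rec$x_A
  Tt <- rec$T

  ssr <- function(par) {
    f <- dimeric_fraction(Tt, exp(par[1]))
    sum((y - f * par[2])^2)
  }
  # coarse profile over log K for a robust start: at fixed K the optimal
  # E_intrinsic is the through-origin slope of y on f_D
  logK_grid <- seq(-14, 4, by = 0.5)
  prof <- vapply(logK_grid, function(lk) {
    f <- dimeric_fraction(Tt, exp(lk))
    Eh <- min(max(sum(f * y) / sum(f^2), 1e-4), 1 - 1e-4)
    sum((y - f * Eh)^2)
  }, numeric(1))
  lk0 <- logK_grid[which.min(prof)]
  f0 <- dimeric_fraction(Tt, exp(lk0))
  E0 <- min(max(sum(f0 * y) / sum(f0^2), 1e-3), 1 - 1e-3)

  lower <- c(-16, 1e-6)
  upper <- c(6, 1 - 1e-6)
  opt <- stats::optim(c(lk0, E0), ssr, method = "L-BFGS-B",
                      lower = lower, upper = upper, hessian = TRUE,
                      control = list(factr = 1e4, maxit = 500))
  logK <- opt$par[1]
  E_int <- opt$par[2]
  at_bound <- logK <= lower[1] + 1e-6 || logK >= upper[1] - 1e-6 ||
    E_int <= lower[2] * 2 || E_int >= upper[2]
  converged <- opt$convergence == 0 && !at_bound
  if (logK >= upper[1] - 1)
    warning("association constant at/near its upper bound: the data show ",
            "little concentration dependence; consider the ",
            "constitutive-dimer analysis", call. = FALSE)
  if (!converged && opt$convergence != 0)
    warning("optimizer did not report convergence (code ", opt$convergence,
            ")", call. = FALSE)

  sigma2 <- opt$value / max(n - 2, 1)
  covm <- tryCatch(2 * sigma2 * solve(opt$hessian),
                   error = function(e) matrix(NA_real_, 2, 2))
  se_logK <- sqrt(max(covm[1, 1], 0))
  se_E <- sqrt(max(covm[2, 2], 0))

  K <- exp(logK)
  K_diss <- 1 / K
  delta_G <- dimerization_free_energy(K_diss, RT)
  se_G <- RT * se_logK  # exact: delta_G is linear in log K
  fitted <- dimeric_fraction(Tt, K) * E_int
  structure(list(
    K = K, K_diss = K_diss,
    E_intrinsic = E_int,
    se_K = K * se_logK, se_logK = se_logK, se_E = se_E,
    ci67_K_diss = sort(exp(c(-logK - se_logK, -logK + se_logK))),
    ci67_E = c(E_int - se_E, E_int + se_E),
    delta_G = delta_G, se_delta_G = se_G,
    ci67_delta_G = c(delta_G - se_G, delta_G + se_G),
    RT = RT, R0 = R0,
    d = intrinsic_fret_to_distance(E_int, R0),
    n_vesicles = n, converged = converged,
    ssr = opt$value, residuals = y - fitted, fitted = fitted,
    data = rec), class = "EquilibriumFit")
}

#' @export
print.EquilibriumFit <- function(x, ...) {
  cat("Monomer-dimer equilibrium fit\n")
  cat(sprintf("  n vesicles  : %d (converged: %s)\n", x$n_vesicles,
              x$converged))
  cat(sprintf("  K_diss      : %.3g receptors/um^2 (67%% CI %.3g to %.3g)\n",
              x$K_diss, x$ci67_K_diss[1], x$ci67_K_diss[2]))
  cat(sprintf("  delta G     : %.1f kcal/mol (67%% CI %.1f to %.1f)\n",
              x$delta_G, x$ci67_delta_G[1], x$ci67_delta_G[2]))
  cat(sprintf("  Intrinsic FRET: %.2f (67%% CI %.2f to %.2f)\n",
              x$E_intrinsic, x$ci67_E[1], x$ci67_E[2]))
  cat(sprintf("  d           : %.1f A (R0 = %.1f A)\n", x$d, x$R0))
  invisible(x)
}

#' Dimeric fraction over a physiological expression range
#'
#' Evaluates the fitted mass-action curve at the endpoints of a receptor
#' surface-concentration range (default 10 to 100 receptors um^-2, the range
#' reported for endothelial-cell expression of 10^4 to 10^5 receptors per
#' cell).
#'
#' @param fit An `EquilibriumFit`, or a `K_diss` value.
#' @param T_range Length-2 concentration range (receptors um^-2); normalized
#'   to increasing order.
#' @return Named numeric `c(f_D_low, f_D_high)`.
#' @export
dimeric_fraction_at_physiological_density <- function(fit,
                                                      T_range = c(10, 100)) {
  K <- if (inherits(fit, "EquilibriumFit")) fit$K else 1 / fit
  T_range <- sort(as.numeric(T_range))
  c(f_D_low = dimeric_fraction(T_range[1], K),
    f_D_high = dimeric_fraction(T_range[2], K))
}
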