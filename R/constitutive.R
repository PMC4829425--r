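#' Per-vesicle Intrinsic FRET for constitutive dimers
#'
#' When a receptor population is fully dimeric across the observed
#' concentration range (no concentration dependence of the corrected FRET),
#' the dimeric fraction is 1 and each vesicle directly reports the Intrinsic
#' FRET as `E_D / x_A`. This function computes the per-vesicle values,
#' histograms them, and fits a single Gaussian to the histogram by least
#' squares, returning the center (the population Intrinsic FRET), the width,
#' and the implied donor-acceptor distance.
#'
#' Vesicles with acceptor fractions outside `xa_bounds` are excluded: the
#' division by `x_A` amplifies noise at extreme donor/acceptor ratios.
#' If a secondary histogram peak exceeds `secondary_peak_fraction` of the main
#' peak, a multimodality warning is issued.
#'
#' @param records Per-vesicle table with `E_D` and `x_A` (flagged rows
#'   ignored).
#' @param bin_width Histogram bin width on the efficiency scale.
#' @param xa_bounds Acceptor-fraction inclusion window.
#' @param secondary_peak_fraction Threshold for the multimodality warning.
#' @param min_records Minimum usable vesicle count (default 20).
#' @param R0 Förster radius (Angstrom) for the distance conversion.
#' @return An object of class `ConstitutiveFit` with the per-vesicle values,
#'   `gaussian_center`, `gaussian_sigma`, the standard error of the mean
#'   `sem`, the distance `d`, and the histogram (`breaks`, `counts`).
#' @export
constitutive_intrinsic_fret <- function(records, bin_width = 0.02,
                                        xa_bounds = c(0.05, 0.95),
                                        secondary_peak_fraction = 0.5,
                                        min_records = 20L, R0 = 53.1) {
  rec <- usable_fret_records(records, xa_bounds = xa_bounds)
  n <- nrow(rec)
  if (n < min_records)
    stop(sprintf("constitutive analysis needs >= %d usable records, got %d",
                 min_records, n), call. = FALSE)
  Ei <- rec$E_D / rec$x_A

  lo <- floor(min(Ei) / bin_width) * bin_width
  hi <- ceiling(max(Ei) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(Ei, breaks = breaks, plot = FALSE)
  mids <- h$mids
  counts <- h$counts

  # multimodality screen on a lightly smoothed histogram: two local maxima
  # count as separate modes only if the valley between them drops below half
  # of the smaller peak (adjacent-bin count jitter is not bimodality)
  if (length(counts) >= 5L) {
    sm <- stats::filter(counts, c(0.25, 0.5, 0.25), sides = 2)
    sm[is.na(sm)] <- counts[is.na(sm)]
    sm <- as.numeric(sm)
    pk <- which(sm > c(-Inf, sm[-length(sm)]) & sm >= c(sm[-1], -Inf))
    if (length(pk) >= 2L) {
      ord <- pk[order(sm[pk], decreasing = TRUE)]
      main <- ord[1]
      for (p in ord[-1]) {
        valley <- min(sm[seq(min(main, p), max(main, p))])
        if (sm[p] > secondary_peak_fraction * sm[main] &&
            valley < 0.5 * sm[p]) {
          warning("Intrinsic FRET histogram looks multimodal (secondary ",
                  sprintf("peak at %.0f%% of the main peak)",
                          100 * sm[p] / sm[main]), call. = FALSE)
          break
        }
      }
    }
  }

  mu0 <- mean(Ei)
  sd0 <- stats::sd(Ei)
  center <- mu0
  sigma <- if (is.finite(sd0) && sd0 > 0) sd0 else bin_width / sqrt(12)
  fit_ok <- FALSE
  if (sum(counts > 0) >= 3L && is.finite(sd0) && sd0 > 0) {
    gfit <- tryCatch(
      minpack.lm::nlsLM(
        counts ~ A * exp(-(mids - mu)^2 / (2 * s^2)),
        start = list(A = max(counts), mu = mu0, s = sd0),
        lower = c(0, lo, bin_width / 100),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(gfit)) {
      cf <- stats::coef(gfit)
      if (cf[["mu"]] >= min(Ei) && cf[["mu"]] <= max(Ei)) {
        center <- cf[["mu"]]
        sigma <- abs(cf[["s"]])
        fit_ok <- TRUE
      }
    }
  }
  structure(list(per_vesicle_E_intrinsic = Ei,
                 gaussian_center = center, gaussian_sigma = sigma,
                 sem = stats::sd(Ei) / sqrt(n),
                 gaussian_fitted = fit_ok,
                 d = intrinsic_fret_to_distance(min(max(center, 1e-6),
                                                    1 - 1e-6), R0),
                 R0 = R0, n_vesicles = n,
                 breaks = breaks, counts = counts, mids = mids),
            class = "ConstitutiveFit")
}

#' @export
print.ConstitutiveFit <- function(x, ...) {
  cat("Constitutive-dimer Intrinsic FRET\n")
  cat(sprintf("  n vesicles     : %d\n", x$n_vesicles))
  cat(sprintf("  Gaussian center: %.3f (sigma %.3f, SEM %.3f)\n",
              x$gaussian_center, x$gaussian_sigma, x$sem))
  cat(sprintf("  d              : %.1f A (R0 = %.1f A)\n", x$d, x$R0))
  invisible(x)
}

#' Test for concentration dependence of the corrected FRET
#'
#' Regresses `E_D / x_A` on `log10(T)` across usable vesicles. A slope
#' significantly different from zero indicates a monomer-dimer equilibrium
#' (the dimeric fraction, hence the normalized FRET, grows with
#' concentration); an insignificant slope indicates constitutive dimerization.
#' With fewer than `min_records` records or less than `min_log10_spread`
#' decades of spread in `T` the data cannot distinguish the regimes and the
#' decision is `"undecidable"`.
#'
#' @param records Per-vesicle table with `E_D`, `x_A`, `T`.
#' @param alpha Significance level for the slope test.
#' @param min_records Minimum usable records.
#' @param min_log10_spread Minimum spread of `log10(T)` (decades).
#' @return A list of class `ModeDecision` with `decision` (`"equilibrium"`,
#'   `"constitutive"` or `"undecidable"`), `slope`, `statistic` (t value),
#'   `p_value`, `alpha` and `n`.
#' @export
detect_concentration_dependence <- function(records, alpha = 0.05,
                                            min_records = 10L,
                                            min_log10_spread = 0.5) {
  rec <- usable_fret_records(records)
  n <- nrow(rec)
  out <- list(decision = "undecidable", slope = NA_real_,
              statistic = NA_real_, p_value = NA_real_, alpha = alpha, n = n)
  class(out) <- "ModeDecision"
  if (n < min_records) {
    out$reason <- sprintf("only %d usable records", n)
    return(out)
  }
  lt <- log10(rec$T)
  if (diff(range(lt)) < min_log10_spread) {
    out$reason <- sprintf("log10(T) spread %.2f below %.2f decades",
                          diff(range(lt)), min_log10_spread)
    return(out)
  }
  y <- rec$E_D / rec$x_A
  fit <- stats::lm(y ~ lt)
  sm <- summary(fit)$coefficients
  out$slope <- sm["lt", "Estimate"]
  out$statistic <- sm["lt", "t value"]
  out$p_value <- sm["lt", "Pr(>|t|)"]
  out$decision <- if (out$p_value < alpha) "equilibrium" else "constitutive"
  out
}

#' @export
print.ModeDecision <- function(x, ...) {
  cat(sprintf("Concentration-dependence test: %s\n", x$decision))
  if (is.finite(x$slope))
    cat(sprintf(paste0("  slope of E_D/x_A vs log10(T): %.4g ",
                       "(t = %.2f, p = %.3g, alpha = %g, n = %d)\n"),
                x$slope, x$statistic, x$p_value, x$alpha, x$n))
  else if (!is.null(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' Bin measured dimeric fractions for display
#'
#' Per-vesicle dimeric fractions `f_D = E_D / (x_A * E_intrinsic)` (clipped to
#' `[0, 1]`) are binned in log-spaced total-concentration bins; per-bin means,
#' standard errors and counts are returned for plotting against the fitted
#' mass-action curve. Binning is for display only and plays no role in
#' fitting. Empty bins are omitted; single-record bins report `NA` standard
#' errors.
#'
#' @param records Per-vesicle table with `E_D`, `x_A`, `T`.
#' @param fit An `EquilibriumFit` (its `E_intrinsic` normalizes the FRET), or
#'   a bare Intrinsic FRET value.
#' @param n_bins Number of log-spaced bins across the observed `T` range.
#' @return A data frame of class `BinnedDimericFractions` with columns
#'   `bin_lo`, `bin_hi`, `bin_mid` (geometric midpoint), `mean_f_D`, `sem`,
#'   `count`.
#' @export
bin_dimeric_fractions <- function(records, fit, n_bins = 10L) {
  E_int <- if (inherits(fit, "EquilibriumFit")) fit$E_intrinsic else
    as.numeric(fit)
  stopifnot(is.finite(E_int), E_int > 0, E_int < 1)
  rec <- usable_fret_records(records)
  if (nrow(rec) == 0L) stop("no usable records to bin", call. = FALSE)
  f_obs <- pmin(1, pmax(0, rec$E_D / (rec$x_A * E_int)))
  lt <- log10(rec$T)
  rng <- range(lt)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- findInterval(lt, edges, rightmost.closed = TRUE, all.inside = TRUE)
  rows <- lapply(sort(unique(idx)), function(b) {
    v <- f_obs[idx == b]
    data.frame(bin_lo = 10^edges[b], bin_hi = 10^edges[b + 1L],
               bin_mid = 10^((edges[b] + edges[b + 1L]) / 2),
               mean_f_D = mean(v),
               sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
                     else NA_real_,
               count = length(v))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("BinnedDimericFractions", class(out))
  out
}
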