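#' Per-donor FRET efficiency from fixed acceptor distances
#'
#' For a donor with acceptors at distances `r` (Angstrom), the transfer rate
#' sum relative to the donor decay rate is `S = sum((R0/r)^6)` and the donor's
#' transfer efficiency is `S / (1 + S)`. A single acceptor at `r = R0` gives
#' efficiency 0.5. This kinetic superposition is the elementary quantity the
#' proximity-FRET Monte Carlo averages over random acceptor configurations.
#'
#' @param r Numeric vector of donor-acceptor distances (Angstrom), all > 0.
#' @param R0 Förster radius (Angstrom). Default 53.1, the YFP/mCherry value.
#' @return Transfer efficiency in `[0, 1)`; 0 for an empty distance vector.
#' @export
donor_transfer_efficiency <- function(r, R0 = 53.1) {
  if (length(r) == 0L) return(0)
  if (any(r <= 0)) stop("distances must be positive", call. = FALSE)
  S <- sum((R0 / r)^6)
  S / (1 + S)
}

#' Monte-Carlo settings for the proximity-FRET estimator
#'
#' @param n_donors Donors simulated per replicate (each donor sees an
#'   independent acceptor configuration).
#' @param n_replicates Independent replicates; the reported Monte-Carlo
#'   standard error is the standard error of the replicate means.
#' @param seed Integer seed; every stochastic routine in the package requires
#'   an explicit seed.
#' @return A list of class `mc_settings`.
#' @export
proximity_mc_settings <- function(n_donors = 10000L, n_replicates = 5L,
                                  seed = 1L) {
  stopifnot(n_donors >= 1, n_replicates >= 1, is.finite(seed))
  structure(list(n_donors = as.integer(n_donors),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "mc_settings")
}

#' Simulate proximity (stochastic/bystander) FRET at one acceptor density
#'
#' Proximity FRET is the efficiency a donor picks up from random, unbound
#' acceptors that happen to lie within transfer range in the two-dimensional
#' membrane. Each simulated donor sees acceptors drawn from a homogeneous
#' spatial Poisson process at the given surface density, restricted to the
#' annulus between `exclusion_radius` (hard-core minimum approach) and
#' `cutoff` (beyond which `(R0/r)^6` is negligible). The per-donor efficiency
#' is `S/(1+S)` with `S = sum((R0/r_j)^6)`; the estimate is the grand mean
#' over donors, averaged across replicates. Donor positions do not matter
#' (donors do not transfer to each other), so each donor is taken as the
#' origin of its own acceptor field.
#'
#' @param acceptor_density Acceptor surface density (receptors um^-2), >= 0.
#' @param R0 Förster radius (Angstrom).
#' @param exclusion_radius Minimum donor-acceptor distance (Angstrom).
#' @param cutoff Maximum acceptor distance considered (Angstrom). 300 A keeps
#'   every pair contributing more than ~3e-5 efficiency at R0 = 53.1 A.
#' @param mc_settings A [proximity_mc_settings()].
#' @return A list with `E_prox` (mean efficiency), `mc_se` (standard error
#'   across replicates, NA for a single replicate) and the settings used.
#' @export
simulate_proximity_fret <- function(acceptor_density, R0 = 53.1,
                                    exclusion_radius = 10, cutoff = 300,
                                    mc_settings = proximity_mc_settings()) {
  if (!is.finite(acceptor_density) || acceptor_density < 0)
    stop("acceptor density must be finite and non-negative", call. = FALSE)
  if (exclusion_radius < 0) stop("exclusion radius must be >= 0", call. = FALSE)
  if (cutoff <= exclusion_radius)
    stop("cutoff must exceed the exclusion radius", call. = FALSE)
  dens_A2 <- acceptor_density * 1e-8  # receptors per square Angstrom
  lambda <- dens_A2 * pi * (cutoff^2 - exclusion_radius^2)
  if (lambda > 1e4)
    stop("acceptor density too high for the current cutoff; reduce the ",
         "cutoff or the density", call. = FALSE)
  if (acceptor_density == 0)
    return(list(E_prox = 0, mc_se = 0, acceptor_density = acceptor_density,
                R0 = R0, exclusion_radius = exclusion_radius, cutoff = cutoff,
                mc_settings = mc_settings))
  set.seed(mc_settings$seed)
  nd <- mc_settings$n_donors
  rep_means <- vapply(seq_len(mc_settings$n_replicates), function(rep) {
    n_acc <- stats::rpois(nd, lambda)
    total <- sum(n_acc)
    if (total == 0) return(0)
    # radius pdf proportional to r on [exclusion_radius, cutoff]
    u <- stats::runif(total)
    r <- sqrt(exclusion_radius^2 + u * (cutoff^2 - exclusion_radius^2))
    contrib <- (R0 / r)^6
    donor <- rep.int(seq_len(nd), n_acc)
    S <- numeric(nd)
    sums <- rowsum(contrib, donor)
    S[as.integer(rownames(sums))] <- sums[, 1L]
    mean(S / (1 + S))
  }, numeric(1))
  mc_se <- if (length(rep_means) > 1L)
    stats::sd(rep_means) / sqrt(length(rep_means)) else NA_real_
  list(E_prox = mean(rep_means), mc_se = mc_se,
       acceptor_density = acceptor_density, R0 = R0,
       exclusion_radius = exclusion_radius, cutoff = cutoff,
       mc_settings = mc_settings)
}

#' Tabulate the proximity-FRET curve over a density grid
#'
#' Runs [simulate_proximity_fret()] at each grid density (seed offset by the
#' grid index so points are independent but reproducible) and stores the
#' resulting curve for fast interpolation by [correct_fret()]. Monte-Carlo
#' jitter is removed by isotonic regression, so the stored curve is
#' non-decreasing in density as the physics requires; a density of zero is
#' pinned to zero efficiency.
#'
#' @inheritParams simulate_proximity_fret
#' @param density_grid Sorted non-negative acceptor densities
#'   (receptors um^-2).
#' @return An object of class `ProximityModel` with elements `density_grid`,
#'   `E_prox_curve` (monotone), `E_prox_raw`, `mc_se`, plus the physical and
#'   Monte-Carlo settings.
#' @export
build_proximity_curve <- function(R0 = 53.1, exclusion_radius = 10,
                                  density_grid = c(0, 25, 50, 100, 200, 400,
                                                   700, 1000, 1500, 2000),
                                  cutoff = 300,
                                  mc_settings = proximity_mc_settings()) {
  if (is.unsorted(density_grid, strictly = TRUE))
    stop("density grid must be strictly increasing", call. = FALSE)
  if (any(density_grid < 0))
    stop("density grid must be non-negative", call. = FALSE)
  sims <- lapply(seq_along(density_grid), function(i) {
    ms <- mc_settings
    ms$seed <- mc_settings$seed + i - 1L
    simulate_proximity_fret(density_grid[i], R0 = R0,
                            exclusion_radius = exclusion_radius,
                            cutoff = cutoff, mc_settings = ms)
  })
  raw <- vapply(sims, `[[`, numeric(1), "E_prox")
  se <- vapply(sims, `[[`, numeric(1), "mc_se")
  curve <- if (length(raw) > 1L) stats::isoreg(density_grid, raw)$yf else raw
  curve[density_grid == 0] <- 0
  structure(list(R0 = R0, exclusion_radius = exclusion_radius,
                 cutoff = cutoff, density_grid = density_grid,
                 E_prox_curve = curve, E_prox_raw = raw, mc_se = se,
                 mc_settings = mc_settings),
            class = "ProximityModel")
}

#' @export
print.ProximityModel <- function(x, ...) {
  cat(sprintf(paste0("Proximity-FRET curve: %d densities in [%g, %g] ",
                     "receptors/um^2\n"),
              length(x$density_grid), min(x$density_grid),
              max(x$density_grid)))
  cat(sprintf("  R0 = %g A, exclusion radius = %g A, cutoff = %g A\n",
              x$R0, x$exclusion_radius, x$cutoff))
  cat(sprintf("  E_prox range: %.4g to %.4g\n",
              min(x$E_prox_curve), max(x$E_prox_curve)))
  invisible(x)
}

#' Evaluate a proximity curve at arbitrary densities
#'
#' Linear interpolation between grid points (which preserves the curve's
#' monotonicity). Densities beyond the grid maximum are held at the last grid
#' value and marked as extrapolated.
#'
#' @param model A `ProximityModel`.
#' @param density Acceptor densities (receptors um^-2).
#' @return A list with `E_prox` and logical `extrapolated`, both aligned with
#'   `density`.
#' @export
eval_proximity <- function(model, density) {
  stopifnot(inherits(model, "ProximityModel"))
  extrapolated <- density > max(model$density_grid) |
    density < min(model$density_grid)
  E <- stats::approx(model$density_grid, model$E_prox_curve, xout = density,
                     rule = 2)$y
  list(E_prox = E, extrapolated = extrapolated)
}

#' @export
predict.ProximityModel <- function(object, density, ...) {
  eval_proximity(object, density)$E_prox
}

#' Subtract proximity FRET from apparent efficiencies
#'
#' The corrected, interaction-specific efficiency is
#' `E_D = max(0, E - E_prox(C_A))`, with the curve evaluated at each vesicle's
#' own acceptor concentration. Records whose apparent efficiency falls below
#' the proximity prediction by more than `tolerance` are flagged
#' `below_proximity` (they are clipped to zero but should be inspected, since
#' a clean measurement cannot lie below the stochastic floor). Densities
#' beyond the curve's grid are flagged `proximity_extrapolated`.
#'
#' @param records Augmented per-vesicle table from [quantify_vesicles()]
#'   (columns `E` and `C_A` required).
#' @param model A `ProximityModel` from [build_proximity_curve()].
#' @param tolerance Allowed shortfall of `E` below the proximity prediction
#'   before flagging, on the efficiency scale. Default 0.05, matching the
#'   typical per-vesicle efficiency noise.
#' @return `records` with columns `E_prox` and `E_D` added and
#'   `quality_flags` updated.
#' @export
correct_fret <- function(records, model, tolerance = 0.05) {
  stopifnot(inherits(model, "ProximityModel"))
  if (!all(c("E", "C_A") %in% names(records)))
    stop("records must carry columns E and C_A (run quantify_vesicles first)",
         call. = FALSE)
  ev <- eval_proximity(model, records$C_A)
  E_D <- pmax(0, records$E - ev$E_prox)
  below <- !is.na(records$E) & records$E < ev$E_prox - tolerance
  add_flag <- function(old, add, which) {
    ifelse(which, ifelse(nzchar(old), paste(old, add, sep = ","), add), old)
  }
  qf <- if (is.null(records$quality_flags)) rep("", nrow(records)) else
    records$quality_flags
  qf <- add_flag(qf, "below_proximity", below)
  qf <- add_flag(qf, "proximity_extrapolated", ev$extrapolated)
  records$E_prox <- ev$E_prox
  records$E_D <- E_D
  records$quality_flags <- qf
  records
}

#' Read or write a proximity curve file
#'
#' The curve is stored as a two-column tab-separated table (density, E_prox)
#' preceded by `#`-prefixed YAML metadata recording the physical parameters
#' and Monte-Carlo settings needed to regenerate it.
#'
#' @param model A `ProximityModel`.
#' @param path File path.
#' @return `read_proximity_curve` returns a `ProximityModel`;
#'   `write_proximity_curve` returns `path` invisibly.
#' @export
write_proximity_curve <- function(model, path) {
  stopifnot(inherits(model, "ProximityModel"))
  meta <- list(R0 = model$R0, exclusion_radius = model$exclusion_radius,
               cutoff = model$cutoff,
               mc_settings = unclass(model$mc_settings))
  hdr <- paste0("# ", strsplit(yaml::as.yaml(meta), "\n")[[1]])
  body <- utils::capture.output(utils::write.table(
    data.frame(density = model$density_grid, E_prox = model$E_prox_curve,
               E_prox_raw = model$E_prox_raw, mc_se = model$mc_se),
    sep = "\t", quote = FALSE, row.names = FALSE))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_proximity_curve
#' @export
read_proximity_curve <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- yaml::yaml.load(paste(sub("^# ?", "", lines[is_meta]),
                                collapse = "\n"))
  tab <- utils::read.delim(text = paste(lines[!is_meta], collapse = "\n"),
                           sep = "\t")
  structure(list(R0 = meta$R0, exclusion_radius = meta$exclusion_radius,
                 cutoff = meta$cutoff, density_grid = tab$density,
                 E_prox_curve = tab$E_prox, E_prox_raw = tab$E_prox_raw,
                 mc_se = tab$mc_se,
                 mc_settings = do.call(proximity_mc_settings,
                                       meta$mc_settings)),
            class = "ProximityModel")
}
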