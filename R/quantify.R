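#' Convert three-channel intensities into concentrations and FRET efficiency
#'
#' Applies the QI-FRET conversion to each vesicle record. With calibration
#' constants `i_D`, `i_A`, `beta_D`, `beta_A`, `G_F`:
#'
#' * acceptor concentration: `C_A = I_A / i_A`
#' * sensitized emission:    `I_SEN = I_FRET - beta_A I_A - beta_D I_D`
#' * reconstructed donor:    `I_D_corr = I_D + G_F I_SEN`
#' * donor concentration:    `C_D = I_D_corr / i_D`
#' * apparent efficiency:    `E = 1 - I_D / I_D_corr`
#'
#' plus the totals `T = C_D + C_A` and acceptor fraction `x_A = C_A / T`.
#' Intensities are assumed background-corrected (see
#' [extract_membrane_intensity()] for image-based background removal).
#'
#' Noise in the FRET-channel subtraction can push `I_SEN` slightly negative for
#' vesicles with little or no FRET. Values in `(-3 * sigma_background, 0)` are
#' clipped to zero; values below `-3 * sigma_background` are flagged
#' `negative_sensitized` and should be excluded from fitting. When
#' `sigma_background = NULL` (default) it is estimated from the negative tail
#' of the `I_SEN` distribution under a reflected half-normal assumption
#' (`sqrt(mean(I_SEN[I_SEN < 0]^2))`), so genuinely low-FRET records are kept.
#'
#' @param intensities Data frame with columns `vesicle_id`, `I_D`, `I_A`,
#'   `I_FRET` (one row per vesicle, arbitrary units, background-free).
#' @param cal A [calibration_set()].
#' @param sigma_background Standard deviation of the background noise on
#'   `I_SEN`, in intensity units, or `NULL` to estimate it from the data.
#' @return The input data frame augmented with columns `C_A`, `I_SEN`,
#'   `I_D_corr`, `C_D`, `T`, `x_A`, `E` and `quality_flags` (comma-separated;
#'   empty string when clean). Flags: `negative_sensitized`,
#'   `nonpositive_donor`, `zero_total`.
#' @export
#' @examples
#' cal <- calibration_set(i_D = 5, i_A = 5, beta_D = 0.2, beta_A = 0.1, G_F = 2)
#' tab <- data.frame(vesicle_id = 1, I_D = 3000, I_A = 2000, I_FRET = 1000)
#' quantify_vesicles(tab, cal)
quantify_vesicles <- function(intensities, cal, sigma_background = NULL) {
  stopifnot(inherits(cal, "CalibrationSet"))
  req <- c("I_D", "I_A", "I_FRET")
  miss <- setdiff(req, names(intensities))
  if (length(miss))
    stop("intensity table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"vesicle_id" %in% names(intensities))
    intensities$vesicle_id <- seq_len(nrow(intensities))
  I_D <- intensities$I_D
  I_A <- intensities$I_A
  I_FRET <- intensities$I_FRET
  if (any(!is.finite(c(I_D, I_A, I_FRET))) || any(c(I_D, I_A, I_FRET) < 0))
    stop("all intensities must be finite and non-negative", call. = FALSE)

  I_SEN <- I_FRET - cal$beta_A * I_A - cal$beta_D * I_D
  if (is.null(sigma_background)) {
    neg <- I_SEN[I_SEN < 0]
    sigma_background <- if (length(neg)) sqrt(mean(neg^2)) else 0
  }
  flags <- vector("list", length(I_D))
  too_negative <- I_SEN < -3 * sigma_background
  for (i in which(too_negative)) flags[[i]] <- c(flags[[i]], "negative_sensitized")
  I_SEN_clipped <- pmax(I_SEN, 0)

  I_D_corr <- I_D + cal$G_F * I_SEN_clipped
  # I_D_corr >= I_D >= 0 by construction; zero means no donor signal at all
  bad_donor <- I_D_corr <= 0
  for (i in which(bad_donor)) flags[[i]] <- c(flags[[i]], "nonpositive_donor")

  C_A <- I_A / cal$i_A
  C_D <- I_D_corr / cal$i_D
  E <- ifelse(bad_donor, NA_real_, 1 - I_D / I_D_corr)
  Tt <- C_A + C_D
  zero_total <- Tt == 0
  for (i in which(zero_total)) flags[[i]] <- c(flags[[i]], "zero_total")
  x_A <- ifelse(Tt == 0, NA_real_, C_A / Tt)

  out <- intensities
  out$C_A <- C_A
  out$I_SEN <- I_SEN_clipped
  out$I_D_corr <- I_D_corr
  out$C_D <- C_D
  out$T <- Tt
  out$x_A <- x_A
  out$E <- E
  out$quality_flags <- vapply(flags, function(f)
    paste(unique(f), collapse = ","), character(1))
  out
}

#' @rdname quantify_vesicles
#' @param I_D,I_A,I_FRET Single-vesicle channel intensities.
#' @export
quantify_vesicle <- function(I_D, I_A, I_FRET, cal, sigma_background = 0) {
  quantify_vesicles(data.frame(vesicle_id = 1L, I_D = I_D, I_A = I_A,
                               I_FRET = I_FRET),
                    cal, sigma_background = sigma_background)
}

# TRUE for rows carrying no quality flags (helper used by downstream fits).
is_unflagged <- function(records) {
  qf <- records$quality_flags
  if (is.null(qf)) rep(TRUE, nrow(records)) else !nzchar(qf)
}

#' Read or write a per-vesicle table
#'
#' Per-vesicle tables are tab-separated text with a header row; the same
#' schema is used for raw intensity tables and for the augmented tables
#' produced by [quantify_vesicles()] and [correct_fret()].
#'
#' @param path File path.
#' @param records Data frame to write.
#' @return `read_vesicle_table` returns a data frame; `write_vesicle_table`
#'   returns `path` invisibly.
#' @export
read_vesicle_table <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @rdname read_vesicle_table
#' @export
write_vesicle_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
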