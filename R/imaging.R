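#' Three-channel vesicle image container
#'
#' @param pixels Numeric array `[rows, cols, 3]` of intensities (a.u.).
#' @param pixel_size Physical pixel size (um per pixel), > 0.
#' @param channel_names Channel labels, default donor / acceptor / FRET.
#' @param truth Optional list of ground-truth parameters (set by
#'   [synthesize_vesicle_image()]).
#' @return An object of class `VesicleImage`.
#' @export
vesicle_image <- function(pixels, pixel_size = 0.1,
                          channel_names = c("donor", "acceptor", "fret"),
                          truth = NULL) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != length(channel_names))
    stop("pixels must be an array [rows, cols, channels]", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 channel_names = channel_names, truth = truth),
            class = "VesicleImage")
}

# Bilinear interpolation of matrix `m` at fractional (x = col, y = row)
# positions; points outside the grid return NA.
interp_bilinear <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(NA_real_, length(x))
  ok <- x >= 1 & x <= nc & y >= 1 & y <= nr
  x0 <- pmin(floor(x[ok]), nc - 1L); y0 <- pmin(floor(y[ok]), nr - 1L)
  fx <- x[ok] - x0; fy <- y[ok] - y0
  v00 <- m[cbind(y0, x0)];     v01 <- m[cbind(y0, x0 + 1L)]
  v10 <- m[cbind(y0 + 1L, x0)]; v11 <- m[cbind(y0 + 1L, x0 + 1L)]
  out[ok] <- v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
  out
}

# Mean interpolated intensity on a circle of given center/radius.
ring_mean <- function(m, cx, cy, radius, n_rays = 72L) {
  th <- seq(0, 2 * pi, length.out = n_rays + 1L)[-1L]
  v <- interp_bilinear(m, cx + radius * cos(th), cy + radius * sin(th))
  mean(v, na.rm = TRUE)
}

#' Locate the vesicle ring in an image
#'
#' Plasma-membrane-derived vesicles imaged at their equator appear as bright
#' rings. The ring center is found as the intensity-weighted centroid of the
#' above-background pixels (exact for a symmetric ring), the radius as the
#' peak of the radial intensity profile (with parabolic sub-pixel
#' refinement), and the center is then refined by a local grid search
#' maximizing the mean on-ring intensity. Detection fails when the best ring
#' is not brighter than the background by `min_contrast` times the robust
#' background spread.
#'
#' @param image A `VesicleImage`, or a single-channel matrix.
#' @param channel Channel index to use; `NULL` (default) sums all channels.
#' @param min_contrast Required `(ring mean - background) / mad` ratio.
#' @return A list of class `VesicleContour` with `center` (`c(x, y)`, in
#'   pixel units, x = column), `radius` (pixels) and `contrast`.
#' @export
locate_vesicle <- function(image, channel = NULL, min_contrast = 3) {
  m <- if (inherits(image, "VesicleImage")) {
    if (is.null(channel)) apply(image$pixels, c(1, 2), sum)
    else image$pixels[, , channel]
  } else as.matrix(image)
  bg <- stats::median(m)
  spread <- stats::mad(m)
  if (spread == 0) spread <- stats::sd(m)
  if (!is.finite(spread) || spread == 0)
    stop("vesicle detection failure: image has no contrast", call. = FALSE)
  w <- pmax(m - bg, 0)
  if (sum(w) == 0)
    stop("vesicle detection failure: no above-background signal",
         call. = FALSE)
  cols <- col(m); rows <- row(m)
  cx <- sum(w * cols) / sum(w)
  cy <- sum(w * rows) / sum(w)

  # radial profile in 1-px annuli around the centroid
  r <- sqrt((cols - cx)^2 + (rows - cy)^2)
  rmax <- floor(min(cx - 1, cy - 1, ncol(m) - cx, nrow(m) - cy))
  if (rmax < 3)
    stop("vesicle detection failure: centroid too close to the image edge",
         call. = FALSE)
  bin <- pmin(floor(r) + 1L, rmax + 1L)
  keep <- r <= rmax
  prof <- as.numeric(tapply(m[keep], bin[keep], mean))
  pk <- which.max(prof)
  radius <- pk - 0.5
  if (pk > 1L && pk < length(prof)) {  # parabolic sub-bin refinement
    a <- prof[pk - 1L]; b <- prof[pk]; cc <- prof[pk + 1L]
    den <- a - 2 * b + cc
    if (den < 0) radius <- radius + 0.5 * (a - cc) / den
  }

  # refine the center on a small grid, maximizing mean on-ring intensity
  best <- c(cx, cy, ring_mean(m, cx, cy, radius))
  for (dx in seq(-1.5, 1.5, by = 0.25)) for (dy in seq(-1.5, 1.5, by = 0.25)) {
    v <- ring_mean(m, cx + dx, cy + dy, radius)
    if (is.finite(v) && v > best[3]) best <- c(cx + dx, cy + dy, v)
  }
  contrast <- (best[3] - bg) / spread
  if (!is.finite(contrast) || contrast < min_contrast)
    stop(sprintf(paste0("vesicle detection failure: ring contrast %.2f ",
                        "below threshold %.2f"), contrast, min_contrast),
         call. = FALSE)
  structure(list(center = c(x = best[1], y = best[2]), radius = radius,
                 contrast = contrast),
            class = "VesicleContour")
}

#' Quantify membrane fluorescence from a cross-membrane Gaussian fit
#'
#' Samples the intensity along `n_rays` rays through the vesicle contour,
#' averages the radial profiles, subtracts the background (median intensity
#' in an annulus outside the vesicle) and fits a Gaussian to the averaged
#' cross-membrane profile. The reported intensity is the area under the
#' Gaussian, `amplitude * width * sqrt(2*pi)`, which is proportional to the
#' number of fluorophores per unit membrane area and robust to
#' focus-dependent width changes.
#'
#' @param image A `VesicleImage`.
#' @param contour A `VesicleContour` from [locate_vesicle()].
#' @param channel Channel index (1-based) or name.
#' @param n_rays Number of rays (default 72).
#' @param membrane_width_guess Expected membrane cross-section SD (pixels).
#' @param profile_halfwidth Half-width of the sampled profile (pixels);
#'   default `5 * membrane_width_guess`.
#' @param annulus_offsets Offsets (pixels) beyond the profile outer edge
#'   delimiting the background annulus.
#' @param residual_threshold Maximum allowed RMS residual relative to the
#'   fitted amplitude before the vesicle is flagged.
#' @return A list of class `MembraneProfile` with the averaged `profile`
#'   (data frame `offset`, `intensity`), Gaussian parameters
#'   (`fit_amplitude`, `fit_center`, `fit_width`, `fit_offset` = subtracted
#'   background), `fit_residual`, the integrated `intensity`, and `flagged` /
#'   `flag_reason`.
#' @export
extract_membrane_intensity <- function(image, contour, channel = 1L,
                                       n_rays = 72L,
                                       membrane_width_guess = 2,
                                       profile_halfwidth = NULL,
                                       annulus_offsets = c(2, 6),
                                       residual_threshold = 0.2) {
  stopifnot(inherits(image, "VesicleImage"), inherits(contour,
                                                      "VesicleContour"))
  if (is.character(channel))
    channel <- match(channel, image$channel_names)
  m <- image$pixels[, , channel]
  hw <- if (is.null(profile_halfwidth)) 5 * membrane_width_guess else
    profile_halfwidth
  cx <- contour$center[["x"]]; cy <- contour$center[["y"]]
  R <- contour$radius
  th <- seq(0, 2 * pi, length.out = n_rays + 1L)[-1L]
  offs <- seq(-hw, hw, by = 0.25)

  grid <- expand.grid(offset = offs, theta = th)
  rr <- R + grid$offset
  vals <- interp_bilinear(m, cx + rr * cos(grid$theta),
                          cy + rr * sin(grid$theta))
  prof <- tapply(vals, grid$offset, mean, na.rm = TRUE)
  profile <- data.frame(offset = as.numeric(names(prof)),
                        intensity = as.numeric(prof))

  # background: median on rings outside the profile's outer edge
  bg_radii <- R + hw + seq(annulus_offsets[1], annulus_offsets[2], by = 0.5)
  bg_vals <- unlist(lapply(bg_radii, function(rb)
    interp_bilinear(m, cx + rb * cos(th), cy + rb * sin(th))))
  background <- stats::median(bg_vals, na.rm = TRUE)
  if (!is.finite(background))
    stop("background annulus falls outside the image; enlarge the frame or ",
         "reduce the profile half-width", call. = FALSE)
  profile$intensity <- profile$intensity - background

  flagged <- FALSE; reason <- ""
  A <- mu <- sg <- resid <- NA_real_
  pk <- max(profile$intensity)
  if (!is.finite(pk) || pk <= 0) {
    flagged <- TRUE; reason <- "no membrane signal above background"
  } else {
    gfit <- tryCatch(
      minpack.lm::nlsLM(
        intensity ~ A * exp(-(offset - mu)^2 / (2 * s^2)),
        data = profile,
        start = list(A = pk,
                     mu = profile$offset[which.max(profile$intensity)],
                     s = membrane_width_guess),
        lower = c(0, -hw, 0.1),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(gfit)) {
      flagged <- TRUE; reason <- "Gaussian fit did not converge"
    } else {
      cf <- stats::coef(gfit)
      A <- cf[["A"]]; mu <- cf[["mu"]]; sg <- abs(cf[["s"]])
      resid <- sqrt(mean(stats::residuals(gfit)^2))
      if (A <= 0) {
        flagged <- TRUE; reason <- "non-positive fitted amplitude"
      } else if (resid > residual_threshold * A) {
        flagged <- TRUE
        reason <- sprintf("relative fit residual %.2f above %.2f",
                          resid / A, residual_threshold)
      }
    }
  }
  structure(list(profile = profile, fit_amplitude = A, fit_center = mu,
                 fit_width = sg, fit_offset = background,
                 fit_residual = resid,
                 intensity = if (flagged) NA_real_ else A * sg * sqrt(2 * pi),
                 flagged = flagged, flag_reason = reason),
            class = "MembraneProfile")
}

#' Quantify all three channels of a vesicle image
#'
#' Convenience wrapper: locates the ring on the channel sum, extracts the
#' membrane intensity per channel, and returns one intensity-table row ready
#' for [quantify_vesicles()].
#'
#' @param image A `VesicleImage`.
#' @param vesicle_id Identifier for the output row.
#' @param ... Passed to [extract_membrane_intensity()].
#' @return One-row data frame with `vesicle_id`, `I_D`, `I_A`, `I_FRET`, and
#'   `quality_flags` collecting per-channel extraction flags.
#' @export
quantify_vesicle_image <- function(image, vesicle_id = 1L, ...) {
  contour <- locate_vesicle(image)
  chans <- lapply(seq_along(image$channel_names), function(ch)
    extract_membrane_intensity(image, contour, channel = ch, ...))
  flags <- image$channel_names[vapply(chans, `[[`, logical(1), "flagged")]
  data.frame(vesicle_id = vesicle_id,
             I_D = chans[[1]]$intensity,
             I_A = chans[[2]]$intensity,
             I_FRET = chans[[3]]$intensity,
             quality_flags = if (length(flags))
               paste0("image_", flags, collapse = ",") else "")
}

#' Synthesize a three-channel vesicle image
#'
#' Renders an equatorial vesicle section: per channel, a ring of radius
#' `radius_px` with Gaussian radial cross-section of SD `membrane_width_px`
#' and peak amplitude given by `densities`, on a constant `background`, with
#' optional shot-like (Poisson) or additive Gaussian noise. Ground truth is
#' stored in the returned object.
#'
#' @param radius_px Ring radius in pixels.
#' @param center `c(x, y)` in pixels, or `NULL` for the image center.
#' @param densities Named or length-3 vector of per-channel peak amplitudes
#'   (a.u.), proportional to fluorophores per membrane area.
#' @param membrane_width_px SD of the radial Gaussian cross-section (pixels).
#' @param background Constant background level (a.u.).
#' @param image_size Image side length (pixels).
#' @param pixel_size Pixel size (um).
#' @param noise `"none"`, `"poisson"` or `"gaussian"`.
#' @param noise_sd SD for Gaussian noise.
#' @param seed Integer seed (used when noise is stochastic).
#' @return A `VesicleImage` whose `truth` element records all inputs.
#' @export
synthesize_vesicle_image <- function(radius_px = 30, center = NULL,
                                     densities = c(donor = 100,
                                                   acceptor = 80, fret = 60),
                                     membrane_width_px = 2, background = 10,
                                     image_size = 101L, pixel_size = 0.1,
                                     noise = c("none", "poisson", "gaussian"),
                                     noise_sd = 3, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(radius_px > 0, membrane_width_px > 0)
  n <- as.integer(image_size)
  if (is.null(center)) center <- c((n + 1) / 2, (n + 1) / 2)
  margin <- radius_px + 5 * membrane_width_px + 8  # profile + bg annulus
  if (center[1] - margin < 1 || center[1] + margin > n ||
      center[2] - margin < 1 || center[2] + margin > n)
    stop("vesicle geometry does not fit in the frame (ring plus background ",
         "annulus would leave the image)", call. = FALSE)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  rows <- matrix(seq_len(n), n, n)
  r <- sqrt((cols - center[1])^2 + (rows - center[2])^2)
  if (noise != "none") set.seed(seed)
  px <- array(0, dim = c(n, n, 3))
  for (ch in 1:3) {
    mu <- densities[ch] * exp(-(r - radius_px)^2 /
                                (2 * membrane_width_px^2)) + background
    px[, , ch] <- switch(noise,
      none = mu,
      poisson = matrix(stats::rpois(n * n, mu), n, n),
      gaussian = mu + matrix(stats::rnorm(n * n, sd = noise_sd), n, n))
  }
  vesicle_image(px, pixel_size = pixel_size,
                truth = list(radius_px = radius_px, center = center,
                             densities = densities,
                             membrane_width_px = membrane_width_px,
                             background = background, noise = noise,
                             noise_sd = noise_sd, seed = seed))
}

#' Read or write a vesicle image as multi-page TIFF
#'
#' Channels are written as separate TIFF pages at 16-bit depth; intensities
#' are scaled by `1/65535` on write and restored on read, so values must stay
#' below 65535 a.u.
#'
#' @param image A `VesicleImage`.
#' @param path File path.
#' @param pixel_size Pixel size (um) to attach on read.
#' @return `read_vesicle_tiff` returns a `VesicleImage`;
#'   `write_vesicle_tiff` returns `path` invisibly.
#' @export
write_vesicle_tiff <- function(image, path) {
  stopifnot(inherits(image, "VesicleImage"))
  if (max(image$pixels) >= 65535)
    stop("intensities must be below 65535 a.u. for 16-bit TIFF export",
         call. = FALSE)
  pages <- lapply(seq_len(dim(image$pixels)[3]), function(ch)
    image$pixels[, , ch] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_vesicle_tiff
#' @export
read_vesicle_tiff <- function(path, pixel_size = 0.1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  px <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (ch in seq_along(pages)) px[, , ch] <- pages[[ch]] * 65535
  vesicle_image(px, pixel_size = pixel_size)
}
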