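test_that("ring location is sub-pixel accurate on a clean synthetic vesicle", {
  img <- synthesize_vesicle_image(radius_px = 25, center = c(48, 55),
                                  image_size = 121L)
  contour <- locate_vesicle(img)
  expect_lt(abs(contour$center[["x"]] - 48), 0.5)
  expect_lt(abs(contour$center[["y"]] - 55), 0.5)
  expect_lt(abs(contour$radius - 25), 0.5)
})

test_that("ring location tolerates shot noise within a pixel", {
  img <- synthesize_vesicle_image(radius_px = 25, center = c(48, 55),
                                  image_size = 121L, noise = "poisson",
                                  seed = 2)
  contour <- locate_vesicle(img)
  expect_lt(abs(contour$center[["x"]] - 48), 1)
  expect_lt(abs(contour$center[["y"]] - 55), 1)
  expect_lt(abs(contour$radius - 25), 1)
})

test_that("blank and ringless images fail detection", {
  blank <- vesicle_image(array(5, dim = c(64, 64, 3)))
  expect_error(locate_vesicle(blank), "detection failure")
})

test_that("membrane profile recovers amplitude with exact background cancellation", {
  for (bg in c(0, 10, 200)) {
    img <- synthesize_vesicle_image(radius_px = 30,
                                    densities = c(100, 80, 60),
                                    membrane_width_px = 2, background = bg,
                                    image_size = 121L)
    contour <- locate_vesicle(img)
    prof <- extract_membrane_intensity(img, contour, channel = 1)
    expect_false(prof$flagged)
    expect_equal(prof$fit_offset, bg, tolerance = 1e-6)
    # bilinear sampling blurs the profile slightly (amplitude down, width
    # up by ~2%) but the integrated readout is conserved to ~0.1%
    expect_equal(prof$fit_amplitude, 100, tolerance = 0.03)
    expect_equal(prof$fit_width, 2, tolerance = 0.03)
    expect_equal(prof$intensity, 100 * 2 * sqrt(2 * pi), tolerance = 0.005)
  }
  # background level leaves the reported intensity unchanged
  ints <- vapply(c(0, 10, 200), function(bg) {
    img <- synthesize_vesicle_image(radius_px = 30, background = bg,
                                    image_size = 121L)
    extract_membrane_intensity(img, locate_vesicle(img), 1)$intensity
  }, numeric(1))
  expect_lt(diff(range(ints)) / mean(ints), 1e-3)
})

test_that("noisy profiles recover the amplitude within 5%", {
  img <- synthesize_vesicle_image(radius_px = 30, densities = c(100, 80, 60),
                                  background = 10, image_size = 121L,
                                  noise = "gaussian", noise_sd = 3, seed = 9)
  prof <- extract_membrane_intensity(img, locate_vesicle(img), channel = 1)
  expect_false(prof$flagged)
  expect_lt(abs(prof$fit_amplitude / 100 - 1), 0.05)
})

test_that("reported intensity is linear in membrane density", {
  dens <- c(20, 50, 100, 200, 400)
  ints <- vapply(dens, function(d) {
    img <- synthesize_vesicle_image(radius_px = 30,
                                    densities = rep(d, 3),
                                    image_size = 121L)
    extract_membrane_intensity(img, locate_vesicle(img), 1)$intensity
  }, numeric(1))
  r2 <- summary(lm(ints ~ dens))$r.squared
  expect_gt(r2, 0.99)
  # doubling the density doubles the readout within 1%
  expect_lt(abs(ints[3] / ints[2] - 100 / 50), 0.01 * 2)
})

test_that("a uniform image is flagged at extraction", {
  img <- synthesize_vesicle_image(radius_px = 30, image_size = 121L)
  contour <- locate_vesicle(img)
  flat <- vesicle_image(array(10, dim = c(121, 121, 3)))
  prof <- extract_membrane_intensity(flat, contour, channel = 1)
  expect_true(prof$flagged)
})

test_that("three-channel quantification preserves density ratios", {
  img <- synthesize_vesicle_image(radius_px = 30,
                                  densities = c(donor = 120, acceptor = 60,
                                                fret = 30),
                                  image_size = 121L)
  row <- quantify_vesicle_image(img)
  expect_identical(row$quality_flags, "")
  expect_equal(row$I_D / row$I_A, 2, tolerance = 0.01)
  expect_equal(row$I_A / row$I_FRET, 2, tolerance = 0.01)
})

test_that("vesicle images survive a TIFF round trip", {
  img <- synthesize_vesicle_image(radius_px = 20, image_size = 81L)
  path <- tempfile(fileext = ".tif")
  write_vesicle_tiff(img, path)
  back <- read_vesicle_tiff(path)
  expect_equal(dim(back$pixels), dim(img$pixels))
  # 16-bit quantization: better than 1 part in 6e4 of full scale
  expect_lt(max(abs(back$pixels - img$pixels)), 1.1)
  unlink(path)
})

test_that("impossible geometry is rejected", {
  expect_error(synthesize_vesicle_image(radius_px = 60, image_size = 101L),
               "does not fit")
})
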