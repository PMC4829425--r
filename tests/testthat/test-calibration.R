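test_that("scale factors recover exact proportionality and the hand-computed slope", {
  conc <- c(10, 20, 40, 80)
  donor <- data.frame(concentration = conc, I_D = 5 * conc)
  acceptor <- data.frame(concentration = conc, I_A = 7 * conc)
  sf <- calibrate_scale_factors(donor, acceptor)
  expect_equal(sf$i_D, 5)
  expect_equal(sf$i_A, 7)

  # through-origin least squares, slope = sum(C*I)/sum(C^2) computed by hand:
  # (10*52 + 20*98 + 40*201) / (100 + 400 + 1600) = 10520 / 2100
  donor2 <- data.frame(concentration = c(10, 20, 40), I_D = c(52, 98, 201))
  sf2 <- calibrate_scale_factors(donor2, acceptor)
  expect_equal(sf2$i_D, 10520 / 2100, tolerance = 1e-12)
})

test_that("degenerate standards fail with a diagnostic", {
  good <- data.frame(concentration = c(10, 20), I_A = c(50, 100))
  expect_error(calibrate_scale_factors(
    data.frame(concentration = 10, I_D = 50), good), "at least 2")
  expect_error(calibrate_scale_factors(
    data.frame(concentration = c(0, 0), I_D = c(1, 2)), good), "distinct")
  # all-zero acceptor intensities -> zero slope -> failure
  expect_error(calibrate_scale_factors(
    data.frame(concentration = c(10, 20), I_D = c(50, 100)),
    data.frame(concentration = c(10, 20), I_A = c(0, 0))),
    "non-positive scale factor")
})

test_that("bleed-through slopes recover exact and zero cases", {
  donor_only <- data.frame(I_D = c(100, 200, 400), I_A = 0,
                           I_FRET = 0.2 * c(100, 200, 400))
  acceptor_only <- data.frame(I_D = 0, I_A = c(100, 200, 400), I_FRET = 0)
  bt <- calibrate_bleedthrough(donor_only, acceptor_only)
  expect_equal(bt$beta_D, 0.2)
  expect_equal(bt$beta_A, 0)
})

test_that("bleed-through recovery under 1% noise is within 1% of truth", {
  set.seed(11)
  n <- 50
  I_D <- runif(n, 100, 1000)
  I_A <- runif(n, 100, 1000)
  donor_only <- data.frame(I_D = I_D, I_A = 0,
                           I_FRET = 0.30 * I_D * rlnorm(n, sdlog = 0.01))
  acceptor_only <- data.frame(I_D = 0, I_A = I_A,
                              I_FRET = 0.10 * I_A * rlnorm(n, sdlog = 0.01))
  bt <- calibrate_bleedthrough(donor_only, acceptor_only)
  expect_lt(abs(bt$beta_D / 0.30 - 1), 0.01)
  expect_lt(abs(bt$beta_A / 0.10 - 1), 0.01)
})

test_that("gauge factor round trips noiselessly and under 2% noise", {
  cal <- calibration_set(50, 50, 0.30, 0.10, G_F = 2.0)
  std <- generate_calibration_standards(cal, linked_efficiency = 0.5,
                                        n_linked = 100L, noise = 0, seed = 3)
  G <- calibrate_gauge_factor(std$linked, cal$beta_D, cal$beta_A, 0.5)
  expect_equal(G, 2.0, tolerance = 1e-10)

  std_n <- generate_calibration_standards(cal, linked_efficiency = 0.5,
                                          n_linked = 100L, noise = 0.02,
                                          seed = 3)
  G_n <- calibrate_gauge_factor(std_n$linked, cal$beta_D, cal$beta_A, 0.5)
  expect_lt(abs(G_n / 2.0 - 1), 0.03)
})

test_that("gauge factor rejects invalid efficiency and FRET-free records", {
  rec <- data.frame(I_D = c(100, 200), I_A = c(100, 200),
                    I_FRET = 0.1 * c(100, 200) + 0.3 * c(100, 200))
  expect_error(calibrate_gauge_factor(rec, 0.3, 0.1, 1.2), "\\(0, 1\\)")
  # I_SEN identically zero: no FRET signal
  expect_error(calibrate_gauge_factor(rec, 0.3, 0.1, 0.5),
               "no sensitized emission")
})

test_that("full calibration round trips the generator truth", {
  cal <- default_cal()
  std0 <- generate_calibration_standards(cal, noise = 0, seed = 5)
  rec0 <- calibrate(std0$donor, std0$acceptor, std0$linked,
                    std0$linked_efficiency)
  for (f in names(unclass(cal)))
    expect_equal(rec0[[f]], cal[[f]], tolerance = 1e-10, label = f)

  std1 <- generate_calibration_standards(cal, noise = 0.01, n_linked = 50L,
                                         seed = 5)
  rec1 <- calibrate(std1$donor, std1$acceptor, std1$linked,
                    std1$linked_efficiency)
  for (f in names(unclass(cal)))
    expect_lt(abs(rec1[[f]] / cal[[f]] - 1), 0.02)

  # a single concentration point cannot calibrate
  expect_error(generate_calibration_standards(cal, concentrations = 100) |>
                 (\(s) calibrate(s$donor, s$acceptor, s$linked, 0.5))(),
               "at least 2|distinct")
})

test_that("calibration files round trip through YAML", {
  cal <- default_cal()
  path <- tempfile(fileext = ".yaml")
  write_calibration(cal, path)
  expect_equal(read_calibration(path), cal)
  unlink(path)
})
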