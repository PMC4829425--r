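test_that("dimeric fraction matches the quadratic-root mass-action oracle", {
  Ts <- c(0.01, 0.1, 1, 10, 100, 1000, 1e4)
  Ks <- c(1e-4, 1e-2, 1 / 35, 1, 100)
  for (K in Ks) {
    f <- dimeric_fraction(Ts, K)
    expect_equal(f, dimeric_fraction_oracle(Ts, K), tolerance = 1e-10)
    # defining identity: 2 K M^2 = D with M = (1-f)T, D = fT/2
    expect_equal(2 * K * ((1 - f) * Ts)^2, f * Ts, tolerance = 1e-9)
  }
  # spot value computed independently: T = 100, K = 1/35
  expect_equal(dimeric_fraction(100, 1 / 35),
               dimeric_fraction_oracle(100, 1 / 35), tolerance = 1e-12)
})

test_that("dimeric fraction obeys the mass-action limits and monotonicity", {
  expect_equal(dimeric_fraction(0, 1), 0)
  expect_lt(dimeric_fraction(1e-12, 1), 1e-11)
  expect_gt(dimeric_fraction(100, 1e8), 0.999)
  Ts <- 10^seq(-1, 3, by = 0.25)
  expect_true(all(diff(dimeric_fraction(Ts, 0.05)) > 0))
  Ks <- 10^seq(-4, 2, by = 0.5)
  fK <- vapply(Ks, function(K) dimeric_fraction(50, K), numeric(1))
  expect_true(all(diff(fK) > 0))
  expect_error(dimeric_fraction(10, -1), "positive")
})

test_that("free energy conversion is exact at the standard state and monotone", {
  expect_equal(dimerization_free_energy(1e6), 0)
  Ks <- c(10, 100, 1000, 1e5)
  expect_true(all(diff(dimerization_free_energy(Ks)) > 0))
  expect_error(dimerization_free_energy(-3), "positive")
  expect_equal(delta_delta_g(-3.4, -3.4), 0)
})

test_that("distance map is a strictly decreasing bijection on (0,1)", {
  E <- seq(0.01, 0.99, by = 0.01)
  d <- intrinsic_fret_to_distance(E)
  expect_true(all(diff(d) < 0))
  expect_equal(distance_to_intrinsic_fret(d), E, tolerance = 1e-12)
  expect_equal(intrinsic_fret_to_distance(0.5), 53.1)
  expect_error(intrinsic_fret_to_distance(1.2), "\\(0, 1\\)")
  expect_error(distance_to_intrinsic_fret(-1), "positive")
})

test_that("noiseless records return the generating parameters", {
  cfg <- synthetic_config(K_diss = 300, E_intrinsic = 0.6, sigma_E = 0,
                          sigma_rel = 0, n_vesicles = 200L, seed = 12)
  fx <- synth_corrected(cfg)
  fit <- fit_monomer_dimer(fx$records)
  expect_equal(fit$K_diss, 300, tolerance = 1e-4)
  expect_equal(fit$E_intrinsic, 0.6, tolerance = 1e-6)
  expect_true(fit$converged)
  # normalized FRET never exceeds the Intrinsic FRET
  expect_true(all(fx$records$E_D / fx$records$x_A <=
                    fit$E_intrinsic + 1e-9))
})

test_that("noisy recovery lands near the truth at campaign scale", {
  # moderate efficiency noise keeps the zero-bound truncation of the noise
  # distribution negligible; the heavier-noise regime is exercised by the
  # acceptance suite, where the truncation-induced bias is characterized
  cfg <- synthetic_config(K_diss = 35, E_intrinsic = 0.82, sigma_E = 0.02,
                          seed = 1)
  fx <- synth_corrected(cfg)
  fit <- fit_monomer_dimer(fx$records)
  expect_lt(abs(fit$delta_G - dimerization_free_energy(35)), 0.3)
  expect_lt(abs(fit$E_intrinsic - 0.82), 0.05)
  expect_true(fit$converged)
})

test_that("degenerate designs are refused with diagnostics", {
  tab <- data.frame(E_D = runif(30, 0, 0.5), x_A = runif(30, 0.2, 0.8),
                    T = 100, quality_flags = "")
  expect_error(fit_monomer_dimer(tab), "identifiable|constitutive")
  few <- data.frame(E_D = 0.1, x_A = 0.5, T = c(10, 100), quality_flags = "")
  expect_error(fit_monomer_dimer(few), ">= 10")
})

test_that("constitutive data push the association constant to its bound", {
  cfg <- synthetic_config(E_intrinsic = 0.45, constitutive = TRUE,
                          sigma_E = 0.04, seed = 23)
  fx <- synth_corrected(cfg)
  expect_warning(fit_monomer_dimer(fx$records), "constitutive|bound")
})

test_that("physiological-density evaluation matches the oracle and handles edge cases", {
  phys <- dimeric_fraction_at_physiological_density(35)
  expect_equal(unname(phys[1]), dimeric_fraction_oracle(10, 1 / 35),
               tolerance = 1e-10)
  expect_equal(unname(phys[2]), dimeric_fraction_oracle(100, 1 / 35),
               tolerance = 1e-10)
  # reversed range is normalized
  expect_equal(dimeric_fraction_at_physiological_density(35, c(100, 10)),
               phys)
  # vanishing association
  tiny <- dimeric_fraction_at_physiological_density(1e12)
  expect_lt(max(tiny), 1e-9)
})

test_that("binned dimeric fractions summarize the model faithfully", {
  cfg <- synthetic_config(K_diss = 35, E_intrinsic = 0.82, sigma_E = 0,
                          sigma_rel = 0, n_vesicles = 200L, seed = 6)
  fx <- synth_corrected(cfg)
  fit <- fit_monomer_dimer(fx$records)
  b <- bin_dimeric_fractions(fx$records, fit, n_bins = 8)
  # noiseless data: per-bin means must lie within the model's range over
  # the bin
  for (i in seq_len(nrow(b))) {
    flo <- dimeric_fraction(b$bin_lo[i], fit$K)
    fhi <- dimeric_fraction(b$bin_hi[i], fit$K)
    expect_gte(b$mean_f_D[i], flo - 1e-6)
    expect_lte(b$mean_f_D[i], fhi + 1e-6)
  }
  expect_true(all(diff(b$mean_f_D) > 0))
  expect_true(all(b$count >= 1))
  expect_true(all(b$mean_f_D >= 0 & b$mean_f_D <= 1))

  # single record: one bin, missing SEM
  one <- data.frame(E_D = 0.2, x_A = 0.5, T = 50, quality_flags = "")
  b1 <- bin_dimeric_fractions(one, 0.8, n_bins = 5)
  expect_equal(nrow(b1), 1L)
  expect_true(is.na(b1$sem))
  expect_equal(b1$count, 1L)
})

test_that("noisy binned means still rise with concentration", {
  for (s in c(31, 32, 33)) {
    cfg <- synthetic_config(K_diss = 35, E_intrinsic = 0.82, seed = s)
    fx <- synth_corrected(cfg)
    fit <- fit_monomer_dimer(fx$records)
    b <- bin_dimeric_fractions(fx$records, fit, n_bins = 6)
    viol <- diff(b$mean_f_D) < -(b$sem[-1] + b$sem[-nrow(b)])
    expect_true(all(!viol, na.rm = TRUE))
  }
})
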